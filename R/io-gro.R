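#' Write a site configuration as a gro coordinate file
#'
#' Fixed-column gro format: title, atom count, one
#' \code{\%5d\%-5s\%5s\%5d\%8.3f\%8.3f\%8.3f} record per site (positions in
#' nm, 3 decimals), and the box vector line. Residue names: \code{HPO} for
#' H2O2, \code{SOL} for water.
#'
#' @param config a \code{\link{site_configuration}}, or a
#'   \code{conformation} (written as one H2O2 molecule in a 3 nm cube).
#' @param path output path.
#' @param title title line.
#' @return \code{path}, invisibly.
#' @export
write_gro <- function(config, path, title = "peroxff configuration") {
  if (inherits(config, "conformation") ||
      (is.matrix(config) && nrow(config) == 4))
    config <- conformation_to_sites(config)
  s <- config$sites
  res <- ifelse(s$species == "H2O2", "HPO", "SOL")
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  s$molecule %% 1e5, res, substr(s$name, 1, 5),
                  seq_len(nrow(s)) %% 1e5, s$x, s$y, s$z)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(title, sprintf("%5d", nrow(s)), recs,
               sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2],
                       config$box[3])), con, sep = "\n")
  invisible(path)
}

#' Read a gro coordinate file into a site configuration
#'
#' Species are inferred from the residue name (\code{HPO} -> H2O2, anything
#' else -> H2O) and elements from the first letter of the atom name.
#'
#' @param path gro file path.
#' @return A \code{\link{site_configuration}}.
#' @export
read_gro <- function(path) {
  raw <- readLines(path)
  if (length(raw) < 3) stop("empty or truncated gro file: ", path)
  n <- suppressWarnings(as.integer(trimws(raw[2])))
  if (is.na(n) || length(raw) < n + 3) stop("malformed gro file: ", path)
  recs <- raw[3:(2 + n)]
  resnr <- as.integer(substr(recs, 1, 5))
  resname <- trimws(substr(recs, 6, 10))
  atom <- trimws(substr(recs, 11, 15))
  x <- as.numeric(substr(recs, 21, 28))
  y <- as.numeric(substr(recs, 29, 36))
  z <- as.numeric(substr(recs, 37, 44))
  if (any(is.na(c(x, y, z)))) stop("malformed coordinates in ", path)
  box <- as.numeric(strsplit(trimws(raw[n + 3]), "[[:space:]]+")[[1]])[1:3]
  site_configuration(
    data.frame(molecule = resnr,
               species = ifelse(resname == "HPO", "H2O2", "H2O"),
               name = atom,
               element = ifelse(substr(atom, 1, 1) == "O", "O", "H"),
               x = x, y = y, z = z),
    box)
}

#' Turn a single-molecule conformation into a site configuration
#'
#' @param conf a \code{conformation}.
#' @param molecule molecule id.
#' @param box box lengths, nm.
#' @return A \code{\link{site_configuration}}.
#' @export
conformation_to_sites <- function(conf, molecule = 1, box = c(3, 3, 3)) {
  conf <- as_conformation(conf)
  site_configuration(
    data.frame(molecule = molecule, species = "H2O2",
               name = rownames(conf),
               element = substr(rownames(conf), 1, 1),
               x = conf[, 1], y = conf[, 2], z = conf[, 3]),
    box)
}
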