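#' Read an xvg time-series file
#'
#' Honors the Grace-style comment conventions: lines starting with \code{#}
#' are comments, lines starting with \code{@} are directives; column names
#' are taken from \code{@ sN legend "..."} directives when present (the
#' first column is the abscissa, named from the xaxis label or
#' \code{"time"}).
#'
#' @param path xvg file path.
#' @return data.frame of the numeric columns, named from the legends.
#' @export
read_xvg <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0) stop("empty xvg file: ", path)
  legends <- character()
  xlab <- "time"
  data_lines <- character()
  for (line in raw) {
    t <- trimws(line)
    if (t == "" || startsWith(t, "#")) next
    if (startsWith(t, "@")) {
      m <- regmatches(t, regexec('@\\s*s(\\d+)\\s+legend\\s+"([^"]*)"', t))[[1]]
      if (length(m) == 3) legends[as.integer(m[2]) + 1] <- m[3]
      mx <- regmatches(t, regexec('@\\s*xaxis\\s+label\\s+"([^"]*)"', t))[[1]]
      if (length(mx) == 2) xlab <- mx[2]
      next
    }
    data_lines <- c(data_lines, t)
  }
  if (length(data_lines) == 0) stop("xvg file has no data rows: ", path)
  tok <- strsplit(data_lines, "[[:space:]]+")
  if (length(unique(lengths(tok))) != 1)
    stop("column-count mismatch in ", path)
  mat <- do.call(rbind, lapply(seq_along(tok), function(i) {
    v <- suppressWarnings(as.numeric(tok[[i]]))
    if (any(is.na(v))) stop("non-numeric xvg data near row ", i)
    v
  }))
  df <- as.data.frame(mat)
  nm <- c(make.names(xlab), if (length(legends)) make.names(legends))
  names(df)[seq_along(nm)] <- nm
  df
}

#' Write a data.frame as an xvg file with legends
#'
#' @param df data.frame; the first column is the abscissa.
#' @param path output path.
#' @param title plot title directive.
#' @return \code{path}, invisibly.
#' @export
write_xvg <- function(df, path, title = "peroxff series") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(sprintf('@    title "%s"', title),
           sprintf('@    xaxis label "%s"', names(df)[1]),
           sprintf('@ s%d legend "%s"', seq_len(ncol(df) - 1) - 1,
                   names(df)[-1]))
  body <- do.call(sprintf, c(list(paste(rep("%.8g", ncol(df)),
                                        collapse = " ")),
                             unname(as.list(df))))
  writeLines(c("# generated by peroxff", hdr, body), con, sep = "\n")
  invisible(path)
}
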