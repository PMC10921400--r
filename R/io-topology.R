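fmt6 <- function(x) formatC(x, digits = 6, format = "g")

#' Write the model topology in the GROMACS itp dialect
#'
#' Emits defaults (with fudgeQQ), atomtypes (LJ on oxygen only), the
#' moleculetype with atoms (charges +/- q_H), bonds, angles, the
#' Ryckaert-Bellemans dihedral with the six expanded coefficients, and --
#' under \code{"opls_14_half"} -- the 1-4 pair. Output is deterministic and
#' byte-stable for identical inputs.
#'
#' @param params \code{\link{model_parameters}}.
#' @param fc \code{\link{force_constants}}.
#' @param policy \code{\link{exclusion_policy}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_topology <- function(params, fc = force_constants(),
                           policy = exclusion_policy(), path) {
  k <- phys_constants()
  cf <- expand_rb_coefficients(params$c2)
  lines <- c(
    "; H2O2 4-site model topology",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    paste("1 3 no 1.0", fmt6(policy$fudge_qq)),
    "",
    "[ atomtypes ]",
    "; name mass charge ptype sigma epsilon",
    paste("OP", fmt6(k$m_O), fmt6(-params$q_H), "A",
          fmt6(params$sigma_OO), fmt6(params$eps_OO)),
    paste("HP", fmt6(k$m_H), fmt6(params$q_H), "A 0 0"),
    "",
    "[ moleculetype ]",
    "; name nrexcl",
    "H2O2 3",
    "",
    "[ atoms ]",
    "; nr type resnr residue atom cgnr charge mass",
    paste("1 HP 1 HPO H1 1", fmt6(params$q_H), fmt6(k$m_H)),
    paste("2 OP 1 HPO O1 1", fmt6(-params$q_H), fmt6(k$m_O)),
    paste("3 OP 1 HPO O2 1", fmt6(-params$q_H), fmt6(k$m_O)),
    paste("4 HP 1 HPO H2 1", fmt6(params$q_H), fmt6(k$m_H)),
    "",
    "[ bonds ]",
    "; i j funct b0 kb",
    paste("1 2 1", fmt6(params$d_OH), fmt6(fc$kb_OH)),
    paste("2 3 1", fmt6(params$d_OO), fmt6(fc$kb_OO)),
    paste("3 4 1", fmt6(params$d_OH), fmt6(fc$kb_OH)),
    "",
    "[ angles ]",
    "; i j k funct th0 ka",
    paste("1 2 3 1", fmt6(params$a_HOO), fmt6(fc$ka_HOO)),
    paste("2 3 4 1", fmt6(params$a_HOO), fmt6(fc$ka_HOO)),
    "",
    "[ dihedrals ]",
    "; i j k l funct c0 c1 c2 c3 c4 c5",
    paste("1 2 3 4 3", paste(fmt6(cf), collapse = " ")))
  if (policy$mode == "opls_14_half")
    lines <- c(lines, "", "[ pairs ]", "; i j funct", "1 4 1")
  con <- file(path, "wb")  # fixed newline for byte stability
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a model topology written in this itp dialect
#'
#' Inverse of \code{\link{write_topology}}; tolerant of comments and blank
#' lines. The exclusion policy is inferred from the presence of a
#' \code{[ pairs ]} section (fudgeQQ from \code{[ defaults ]}). RB
#' coefficients are read as given -- conformance to the c0..c5 constraints
#' is a separate check.
#'
#' @param path itp file path.
#' @return \code{list(params, fc, policy, rb_coefficients)}.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("no such topology file: ", path)
  raw <- readLines(path)
  section <- NA_character_
  rows <- list()
  for (i in seq_along(raw)) {
    line <- sub(";.*$", "", raw[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      section <- trimws(gsub("[][]", "", line))
      next
    }
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    rows[[length(rows) + 1]] <- list(section = section, tok = tok, lineno = i)
  }
  get <- function(sec) Filter(function(r) identical(r$section, sec), rows)
  num <- function(x, lineno) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop("malformed topology at line ", lineno)
    v
  }
  atoms <- get("atoms")
  if (length(atoms) != 4) stop("topology must define exactly 4 atoms")
  q <- vapply(atoms, function(r) num(r$tok[7], r$lineno), numeric(1))
  q_H <- q[1]
  at <- get("atomtypes")
  op <- Filter(function(r) r$tok[1] == "OP", at)
  if (length(op) != 1) stop("missing OP atomtype")
  sigma <- num(op[[1]]$tok[5], op[[1]]$lineno)
  eps <- num(op[[1]]$tok[6], op[[1]]$lineno)
  bonds <- get("bonds")
  if (length(bonds) != 3) stop("topology must define 3 bonds")
  bond_of <- function(i, j) {
    b <- Filter(function(r) all(sort(as.integer(r$tok[1:2])) == c(i, j)), bonds)
    if (length(b) != 1) stop("missing bond ", i, "-", j)
    num(b[[1]]$tok[4:5], b[[1]]$lineno)
  }
  oh <- bond_of(1, 2); oo <- bond_of(2, 3)
  angles <- get("angles")
  if (length(angles) < 1) stop("missing angles section")
  ang <- num(angles[[1]]$tok[5:6], angles[[1]]$lineno)
  dih <- get("dihedrals")
  if (length(dih) != 1) stop("parse error: missing dihedral section")
  if (dih[[1]]$tok[5] != "3")
    stop("dihedral funct must be 3 (Ryckaert-Bellemans) at line ",
         dih[[1]]$lineno)
  rb <- num(dih[[1]]$tok[6:11], dih[[1]]$lineno)
  names(rb) <- paste0("c", 0:5)
  defaults <- get("defaults")
  fudge <- if (length(defaults) == 1) num(defaults[[1]]$tok[5],
                                          defaults[[1]]$lineno) else 0.5
  has_pairs <- length(get("pairs")) > 0
  list(params = model_parameters(c2 = rb[["c2"]], q_H = q_H,
                                 sigma_OO = sigma, eps_OO = eps,
                                 d_OO = oo[1], d_OH = oh[1], a_HOO = ang[1]),
       fc = force_constants(kb_OO = oo[2], kb_OH = oh[2], ka_HOO = ang[2]),
       policy = exclusion_policy(if (has_pairs) "opls_14_half"
                                 else "exclude_all_intra", fudge),
       rb_coefficients = rb)
}
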