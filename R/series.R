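#' NPT thermodynamic time series
#'
#' Container for trajectory-derived time series feeding the fluctuation
#' estimators. Columns: time (ps), U (potential energy, kJ/mol, whole box),
#' V (box volume, nm^3), H (enthalpy, kJ/mol, whole box), T (K), P (bar).
#'
#' @param time,U,V,H,T,P equal-length numeric vectors.
#' @param n_molecules number of molecules in the box.
#' @return A data.frame of class \code{thermo_series} with attribute
#'   \code{n_molecules}.
#' @export
thermo_series <- function(time, U, V, H, T, P, n_molecules) {
  n <- length(time)
  if (!all(lengths(list(U, V, H, T, P)) == n))
    stop("all thermo series columns must have equal length")
  if (any(V <= 0)) stop("volumes must be positive")
  if (n_molecules <= 0) stop("n_molecules must be positive")
  ts <- data.frame(time = time, U = U, V = V, H = H, T = T, P = P)
  attr(ts, "n_molecules") <- n_molecules
  class(ts) <- c("thermo_series", "data.frame")
  ts
}

#' Box-dipole time series
#'
#' @param time ps.
#' @param M n x 3 matrix of box dipole vectors, e nm.
#' @param V box volume(s), nm^3 (length 1 or n).
#' @param T temperature(s), K (length 1 or n).
#' @return A list of class \code{dipole_series}.
#' @export
dipole_series <- function(time, M, V, T) {
  M <- as.matrix(M)
  n <- length(time)
  if (nrow(M) != n || ncol(M) != 3) stop("M must be an n x 3 matrix")
  if (any(!is.finite(M)) || any(!is.finite(V)) || any(!is.finite(T)))
    stop("dipole series must be finite")
  structure(list(time = time, M = M, V = rep(V, length.out = n),
                 T = rep(T, length.out = n)),
            class = "dipole_series")
}

# Split 1..n into nb contiguous equal blocks; returns list of index vectors.
block_indices <- function(n, nb) {
  split(seq_len(n), cut(seq_len(n), nb, labels = FALSE))
}

# Mean and standard error over block estimates, discarding blocks more than
# three standard deviations from the block-mean (the block-discard rule).
block_summary <- function(vals) {
  keep <- rep(TRUE, length(vals))
  if (length(vals) >= 3 && stats::sd(vals) > 0) {
    z <- abs(vals - mean(vals)) / stats::sd(vals)
    keep <- z <= 3
  }
  v <- vals[keep]
  list(value = mean(v),
       error = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n_blocks_used = length(v), discarded = sum(!keep))
}
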