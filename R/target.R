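#' Default 22-component property/condition layout
#'
#' The parametrization targets are evaluated for the pure peroxide liquid
#' and the 70 wt percent peroxide-water mixture: density rho (kg/m^3),
#' dielectric constant eps, viscosity mu (cP), vapor pressure P_v (bar),
#' surface tension lambda (mN/m), and - mixture only - the vapor
#' composition wt_v (weight percent), each at one or more temperatures.
#' The reference values \code{x_e} are nominal experimental anchors for the
#' synthetic pipeline; they can be replaced wholesale from configuration.
#'
#' @return data.frame with columns \code{label}, \code{property},
#'   \code{condition} (\code{"pure"}/\code{"mixture"}), \code{T} (K),
#'   \code{x_e}.
#' @export
property_layout <- function() {
  df <- rbind(
    data.frame(property = "rho",    condition = "pure",
               T = c(273, 293, 313, 333), x_e = c(1463, 1443, 1423, 1403)),
    data.frame(property = "eps",    condition = "pure",
               T = c(293, 313), x_e = c(72, 66)),
    data.frame(property = "mu",     condition = "pure",
               T = c(293, 313), x_e = c(1.25, 0.95)),
    data.frame(property = "P_v",    condition = "pure",
               T = c(393, 423), x_e = c(0.35, 1.01)),
    data.frame(property = "lambda", condition = "pure",
               T = c(293, 313), x_e = c(80.5, 77.0)),
    data.frame(property = "rho",    condition = "mixture",
               T = c(273, 293), x_e = c(1310, 1290)),
    data.frame(property = "eps",    condition = "mixture",
               T = 293, x_e = 77),
    data.frame(property = "mu",     condition = "mixture",
               T = 293, x_e = 1.10),
    data.frame(property = "P_v",    condition = "mixture",
               T = c(393, 423), x_e = c(0.9, 2.8)),
    data.frame(property = "lambda", condition = "mixture",
               T = c(293, 313), x_e = c(76, 73)),
    data.frame(property = "wt_v",   condition = "mixture",
               T = c(393, 423), x_e = c(35, 45)))
  df$label <- sprintf("%s_%s_%g", df$property, df$condition, df$T)
  df[, c("label", "property", "condition", "T", "x_e")]
}

#' Target-function weights over the 22 properties/conditions
#'
#' Composition weight wc is 1 for the pure substance and 0.25 for the
#' mixture (to limit dependence on the partner water model); property weight
#' wp is 1 for rho, eps, P_v, lambda (and wt_v) and 0.5 for viscosity.
#'
#' @param layout a \code{\link{property_layout}}-shaped data.frame.
#' @param wc_mixture composition weight for mixture entries.
#' @param wp_viscosity property weight for viscosity entries.
#' @return An object of class \code{target_weights}: the layout plus
#'   \code{wc} and \code{wp} columns.
#' @export
target_weights <- function(layout = property_layout(), wc_mixture = 0.25,
                           wp_viscosity = 0.5) {
  layout$wc <- ifelse(layout$condition == "pure", 1, wc_mixture)
  layout$wp <- ifelse(layout$property == "mu", wp_viscosity, 1)
  if (any(layout$wc <= 0) || any(layout$wp <= 0))
    stop("weights must be positive")
  if (any(layout$x_e == 0)) stop("experimental references must be nonzero")
  structure(layout, class = c("target_weights", "data.frame"))
}

#' Weighted experimental-deviation target function
#'
#' F(x) = sum_i wc_i wp_i ((x_i - x_ei) / x_ei)^2, the weighted sum of
#' squared relative deviations of the 22 predicted properties from their
#' experimental references. F >= 0, with F = 0 iff every property matches
#' its reference.
#'
#' @param x 22-vector (or n x 22 matrix) of property values in the layout
#'   order of \code{weights}.
#' @param weights \code{\link{target_weights}}.
#' @return F (scalar or length-n vector).
#' @export
target_function <- function(x, weights = target_weights()) {
  if (any(!is.finite(x))) stop("property values must be finite")
  w <- weights$wc * weights$wp
  if (is.matrix(x)) {
    if (ncol(x) != nrow(weights)) stop("x has the wrong number of properties")
    rel <- sweep(sweep(x, 2, weights$x_e), 2, weights$x_e, "/")
    drop(rel^2 %*% w)
  } else {
    if (length(x) != nrow(weights)) stop("x has the wrong number of properties")
    sum(w * ((x - weights$x_e) / weights$x_e)^2)
  }
}

#' Global random search over the parameter cube
#'
#' Draws n parameter vectors uniformly in the unit cube, evaluates each
#' surrogate model's predicted properties through the target function, and
#' reports the minimizer per model together with low-F candidates (the
#' F(p) landscape typically has several local minima).
#'
#' @param models a \code{surrogate_model} or list of them.
#' @param weights \code{\link{target_weights}}.
#' @param n number of random samples.
#' @param seed integer seed.
#' @param n_candidates low-F candidates to keep per model.
#' @return A list per model: \code{best_p} (physical units), \code{best_u}
#'   (unit cube), \code{best_F}, and \code{candidates} (data.frame of the
#'   \code{n_candidates} lowest-F samples with their parameters).
#' @export
random_search <- function(models, weights = target_weights(), n = 1e5,
                          seed = 1, n_candidates = 10) {
  if (n < 1) stop("n must be at least 1")
  if (inherits(models, "surrogate_model")) models <- list(models)
  set.seed(seed)
  # row-wise fill: with the same seed the first n samples are a prefix of
  # any larger draw, so the best F is non-increasing in n
  U <- matrix(stats::runif(n * 7), ncol = 7, byrow = TRUE)
  lapply(models, function(m) {
    Fv <- numeric(n)
    for (s in split(seq_len(n), ceiling(seq_len(n) / 1e5))) {
      pred <- predict(m, U[s, , drop = FALSE], normalized = TRUE)
      Fv[s] <- target_function(pred, weights)
    }
    ord <- order(Fv)[seq_len(min(n_candidates, n))]
    best_u <- stats::setNames(U[ord[1], ], param_names())
    cand <- as.data.frame(denormalize_params(U[ord, , drop = FALSE],
                                             m$ranges))
    cand$F <- Fv[ord]
    list(best_p = denormalize_params(best_u, m$ranges), best_u = best_u,
         best_F = Fv[ord[1]], candidates = cand)
  })
}

#' Local stochastic refinement of a parameter vector
#'
#' Greedy random descent: proposals p_try = p + xi (*) delta_p with xi
#' uniform in [-0.5, 0.5]^7 and delta_p a step-magnitude vector with equal
#' nonzero components in normalized space. Proposals falling outside the
#' parameter ranges are rejected (never clamped); an improving proposal
#' becomes the new center, so F never increases across accepted iterations.
#'
#' @param p_start physical 7-vector inside \code{ranges}.
#' @param evaluator function taking a physical named 7-vector and returning
#'   F (e.g. surrogate prediction + \code{\link{target_function}}, or a
#'   direct simulation oracle).
#' @param ranges \code{\link{parameter_ranges}}.
#' @param delta_p step magnitudes in normalized space (scalar or 7-vector).
#' @param n_iter number of proposals.
#' @param seed integer seed.
#' @return A list: \code{p} (best parameters), \code{F}, \code{n_accepted},
#'   \code{n_rejected_range}, and \code{all_rejected} flag (TRUE when every
#'   proposal fell out of range and p_start is returned unchanged).
#' @export
local_refine <- function(p_start, evaluator, ranges = parameter_ranges(),
                         delta_p = 0.1, n_iter = 200, seed = 1) {
  set.seed(seed)
  dp <- rep(delta_p, length.out = 7)
  u <- normalize_params(p_start, ranges)
  best_F <- evaluator(denormalize_params(u, ranges))
  n_acc <- 0L; n_rej <- 0L
  for (i in seq_len(n_iter)) {
    xi <- stats::runif(7, -0.5, 0.5)
    u_try <- u + xi * dp
    if (any(u_try < 0) || any(u_try > 1)) { n_rej <- n_rej + 1L; next }
    if (all(dp == 0)) next
    F_try <- evaluator(denormalize_params(u_try, ranges))
    if (F_try < best_F) {
      u <- u_try; best_F <- F_try; n_acc <- n_acc + 1L
    }
  }
  list(p = denormalize_params(u, ranges), F = best_F, n_accepted = n_acc,
       n_rejected_range = n_rej,
       all_rejected = n_rej == n_iter && n_iter > 0)
}
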