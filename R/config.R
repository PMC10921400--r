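#' Load and validate a run configuration
#'
#' A single YAML document with the optional top-level sections
#' \code{parameters} (the 7 physical parameters), \code{ranges}
#' (\code{lower}/\code{upper} named lists), \code{force_constants},
#' \code{exclusion_policy} (\code{mode}, \code{fudge_qq}), \code{gas}
#' (\code{a_d_min}, \code{u_g_min} to pin the isolated-molecule reference),
#' \code{estimators}, \code{optimizer}, \code{seed} and \code{paths}.
#' Unknown keys are rejected.
#'
#' @param path YAML file path, or NULL for an all-defaults configuration.
#' @return A list of class \code{run_config} with materialized objects:
#'   \code{params}, \code{ranges}, \code{fc}, \code{policy}, \code{gas_ref}
#'   (may be NULL), \code{estimators}, \code{optimizer}, \code{seed},
#'   \code{paths}.
#' @export
run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "ranges", "force_constants", "exclusion_policy",
             "gas", "estimators", "optimizer", "seed", "paths")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  params <- do.call(model_parameters, as.list(raw$parameters %||% list()))
  ranges <- if (is.null(raw$ranges)) parameter_ranges() else
    parameter_ranges(lower = unlist(raw$ranges$lower),
                     upper = unlist(raw$ranges$upper))
  fc <- do.call(force_constants, as.list(raw$force_constants %||% list()))
  policy <- do.call(exclusion_policy, as.list(raw$exclusion_policy %||% list()))
  gas_ref <- if (is.null(raw$gas)) NULL else
    gas_reference(raw$gas$a_d_min %||% 114.9, raw$gas$u_g_min)
  structure(list(params = params, ranges = ranges, fc = fc, policy = policy,
                 gas_ref = gas_ref,
                 estimators = raw$estimators %||% list(),
                 optimizer = raw$optimizer %||% list(),
                 seed = raw$seed %||% 1L,
                 paths = raw$paths %||% list()),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
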