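#' Map physical parameter vectors to the unit cube (and back)
#'
#' Affine per-coordinate normalization bound to \code{\link{parameter_ranges}}:
#' the lower bound maps to 0 and the upper to 1.
#'
#' @param p numeric 7-vector (or n x 7 matrix) of physical parameters in the
#'   order \code{\link{param_names}}.
#' @param ranges \code{\link{parameter_ranges}}.
#' @param tol tolerance for the in-range check.
#' @return Vector/matrix in [0, 1]^7.
#' @export
normalize_params <- function(p, ranges = parameter_ranges(), tol = 1e-12) {
  lo <- ranges$lower; hi <- ranges$upper
  m <- if (is.matrix(p)) p else matrix(as_param_vector(p), nrow = 1,
                                       dimnames = list(NULL, param_names()))
  for (j in seq_len(7)) {
    bad <- m[, j] < lo[j] - tol | m[, j] > hi[j] + tol
    if (any(bad))
      stop("parameter out of range: ", param_names()[j], " = ",
           m[which(bad)[1], j], " not in [", lo[j], ", ", hi[j], "]")
  }
  u <- sweep(sweep(m, 2, lo), 2, hi - lo, "/")
  if (is.matrix(p)) u else stats::setNames(drop(u), param_names())
}

#' @rdname normalize_params
#' @param u unit-cube vector/matrix.
#' @export
denormalize_params <- function(u, ranges = parameter_ranges()) {
  lo <- ranges$lower; hi <- ranges$upper
  m <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  p <- sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
  colnames(p) <- param_names()
  if (is.matrix(u)) p else stats::setNames(drop(p), param_names())
}

#' Parameter-to-property training table
#'
#' @param p n x 7 matrix of physical parameters (columns
#'   \code{\link{param_names}}).
#' @param y n x 22 matrix of property values; column names label the
#'   property/condition layout (see \code{\link{property_layout}}).
#' @param ranges the \code{\link{parameter_ranges}} the rows live in.
#' @return An object of class \code{training_table}.
#' @export
training_table <- function(p, y, ranges = parameter_ranges()) {
  p <- as.matrix(p); y <- as.matrix(y)
  if (nrow(p) != nrow(y)) stop("p and y must have the same number of rows")
  if (ncol(p) != 7) stop("p must have 7 columns")
  if (any(!is.finite(y))) stop("property values must be finite")
  normalize_params(p, ranges)   # validates range membership
  structure(list(p = p, y = y, ranges = ranges), class = "training_table")
}

#' @export
print.training_table <- function(x, ...) {
  cat(sprintf("training_table: %d rows, %d parameters -> %d properties\n",
              nrow(x$p), ncol(x$p), ncol(x$y)))
  invisible(x)
}

#' The fixed 24-architecture grid
#'
#' All combinations of activation (ReLu, Sigm), depth (1-3 hidden layers)
#' and width (2, 4, 8 or 16 neurons per layer).
#'
#' @return data.frame with columns \code{activation}, \code{layers},
#'   \code{N_L}.
#' @export
architecture_grid <- function() {
  expand.grid(activation = c("ReLu", "Sigm"), layers = 1:3,
              N_L = c(2, 4, 8, 16), stringsAsFactors = FALSE)
}

#' Parse an architecture string
#'
#' Architectures follow the notation nonlinear-function/number of
#' layers/N_L, e.g. \code{"ReLu/1/8"} or \code{"Sigm/2/4"}.
#'
#' @param arch architecture string.
#' @return \code{list(activation, layers, N_L)}.
#' @export
parse_architecture <- function(arch) {
  parts <- strsplit(arch, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("architecture must look like 'ReLu/1/8'")
  act <- c(relu = "ReLu", sigm = "Sigm")[tolower(substr(parts[1], 1, 4))]
  layers <- as.integer(parts[2]); N_L <- as.integer(parts[3])
  if (is.na(act) || !(layers %in% 1:3) || !(N_L %in% c(2, 4, 8, 16)))
    stop("architecture outside the grid: activations ReLu/Sigm, 1-3 layers, ",
         "2/4/8/16 neurons per layer")
  list(activation = unname(act), layers = layers, N_L = N_L)
}

mlp_init <- function(sizes, activation) {
  n_layer <- length(sizes) - 1
  lapply(seq_len(n_layer), function(l) {
    fan_in <- sizes[l]
    sd <- if (activation == "ReLu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    # hidden biases start positive: inputs live in [0,1], so this keeps
    # ReLU units active over the whole cube at the start and avoids
    # dead-unit basins (units deactivate later only if the fit wants it)
    b0 <- if (activation == "ReLu" && l < n_layer) 1.5 else 0
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd),
                    fan_in, sizes[l + 1]),
         b = rep(b0, sizes[l + 1]))
  })
}

mlp_forward <- function(layers, X, activation) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l == length(layers)) Z
      else if (activation == "ReLu") pmax(Z, 0)
      else 1 / (1 + exp(-Z))
  }
  acts
}

# full-batch backprop gradient of the MSE loss
mlp_gradient <- function(layers, acts, Y, activation) {
  n <- nrow(Y)
  L <- length(layers)
  grads <- vector("list", L)
  delta <- 2 * (acts[[L + 1]] - Y) / (n * ncol(Y))
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      a <- acts[[l]]
      delta <- if (activation == "ReLu") delta * (a > 0)
               else delta * a * (1 - a)
    }
  }
  grads
}

#' Train a feed-forward surrogate on a training table
#'
#' Small fully connected regressor from the normalized 7-parameter cube to
#' the 22 normalized property values. Full-batch gradient descent with
#' adaptive-moment (Adam) updates and mean-squared-error loss; deterministic
#' given the seed. Output normalization is bound to the training-table
#' column extrema; input normalization to the table's parameter ranges.
#'
#' @param table a \code{\link{training_table}} with at least 50 rows.
#' @param arch architecture string, e.g. \code{"ReLu/1/8"}.
#' @param seed integer seed (weights initialization is the only source of
#'   randomness).
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param validation optional \code{\link{training_table}} monitored for
#'   early stopping (training stops after \code{patience} stale checks,
#'   evaluated every 50 epochs; the best weights are kept).
#' @param patience stale validation checks tolerated before stopping.
#' @return An object of class \code{surrogate_model} with the weights,
#'   normalization, architecture and loss history.
#' @export
train_surrogate <- function(table, arch = "ReLu/1/8", seed = 1,
                            epochs = 3000, lr = 0.01, validation = NULL,
                            patience = 10) {
  if (nrow(table$p) < 50) stop("need at least 50 training rows")
  a <- parse_architecture(arch)
  set.seed(seed)
  X <- normalize_params(table$p, table$ranges)
  ymin <- apply(table$y, 2, min); ymax <- apply(table$y, 2, max)
  yspan <- pmax(ymax - ymin, 1e-12)
  Y <- sweep(sweep(table$y, 2, ymin), 2, yspan, "/")
  sizes <- c(7, rep(a$N_L, a$layers), ncol(Y))
  layers <- mlp_init(sizes, a$activation)
  mom <- lapply(layers, function(l)
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  Xv <- Yv <- NULL
  if (!is.null(validation)) {
    Xv <- normalize_params(validation$p, table$ranges)
    Yv <- sweep(sweep(validation$y, 2, ymin), 2, yspan, "/")
  }
  loss <- numeric(epochs)
  best_val <- Inf; best_layers <- layers; stale <- 0
  for (e in seq_len(epochs)) {
    acts <- mlp_forward(layers, X, a$activation)
    loss[e] <- mean((acts[[length(acts)]] - Y)^2)
    g <- mlp_gradient(layers, acts, Y, a$activation)
    for (l in seq_along(layers)) {
      mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * g[[l]]$W
      mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * g[[l]]$W^2
      mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * g[[l]]$b
      mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * g[[l]]$b^2
      ch <- 1 / (1 - b1^e); cv <- 1 / (1 - b2^e)
      layers[[l]]$W <- layers[[l]]$W -
        lr * (mom[[l]]$mW * ch) / (sqrt(mom[[l]]$vW * cv) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        lr * (mom[[l]]$mb * ch) / (sqrt(mom[[l]]$vb * cv) + eps)
    }
    if (!is.null(Xv) && e %% 50 == 0) {
      pv <- mlp_forward(layers, Xv, a$activation)
      vl <- mean((pv[[length(pv)]] - Yv)^2)
      if (vl < best_val - 1e-9) {
        best_val <- vl; best_layers <- layers; stale <- 0
      } else stale <- stale + 1
      if (stale >= patience) { loss <- loss[seq_len(e)]; break }
    }
  }
  if (!is.null(Xv) && is.finite(best_val)) layers <- best_layers
  structure(list(arch = sprintf("%s/%d/%d", a$activation, a$layers, a$N_L),
                 activation = a$activation, layers = layers,
                 ranges = table$ranges, ymin = ymin, yspan = yspan,
                 labels = colnames(table$y), loss_history = loss,
                 val_loss = if (is.null(Xv)) NA_real_ else best_val),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("surrogate_model %s  final loss %.3g%s\n", x$arch,
              utils::tail(x$loss_history, 1),
              if (is.na(x$val_loss)) "" else sprintf("  val %.3g", x$val_loss)))
  invisible(x)
}

#' Predict properties from a surrogate model
#'
#' @param object a \code{surrogate_model}.
#' @param p physical 7-vector or n x 7 matrix.
#' @param normalized set TRUE when \code{p} is already in the unit cube.
#' @param ... unused.
#' @return n x 22 matrix (or named vector) of property values in physical
#'   units.
#' @export
predict.surrogate_model <- function(object, p, normalized = FALSE, ...) {
  U <- if (normalized) {
    if (is.matrix(p)) p else matrix(p, nrow = 1)
  } else normalize_params(if (is.matrix(p)) p else
    matrix(as_param_vector(p), nrow = 1), object$ranges)
  acts <- mlp_forward(object$layers, U, object$activation)
  Yn <- acts[[length(acts)]]
  Y <- sweep(sweep(Yn, 2, object$yspan, "*"), 2, object$ymin, "+")
  colnames(Y) <- object$labels
  if (is.matrix(p) || (normalized && is.matrix(p))) Y else drop(Y)
}

#' Rank the 24-architecture grid on held-out data
#'
#' Trains every architecture in the grid (ReLu/Sigm x 1-3 layers x
#' 2/4/8/16 neurons) on the training table and reports validation deviations
#' per property on the held-out table.
#'
#' @param train,validation disjoint \code{\link{training_table}}s.
#' @param seed integer seed.
#' @param epochs training epochs per architecture.
#' @return A list with \code{ranking} (data.frame arch, val_rmse, sorted
#'   ascending) and \code{per_property} (24 x 22 matrix of per-property
#'   validation RMSE on the normalized scale).
#' @export
evaluate_architectures <- function(train, validation, seed = 1,
                                   epochs = 1500) {
  if (nrow(train$p) == nrow(validation$p) &&
      isTRUE(all.equal(train$p, validation$p)))
    warning("training and validation tables overlap")
  grid <- architecture_grid()
  archs <- sprintf("%s/%d/%d", grid$activation, grid$layers, grid$N_L)
  per_prop <- matrix(NA_real_, length(archs), ncol(train$y),
                     dimnames = list(archs, colnames(train$y)))
  rmse <- numeric(length(archs))
  for (i in seq_along(archs)) {
    m <- train_surrogate(train, archs[i], seed = seed, epochs = epochs,
                         validation = validation)
    pred <- predict(m, validation$p)
    resid <- sweep(sweep(pred - validation$y, 2, m$yspan, "/"), 2, 0)
    per_prop[i, ] <- sqrt(colMeans(resid^2))
    rmse[i] <- sqrt(mean(resid^2))
  }
  ranking <- data.frame(arch = archs, val_rmse = rmse)
  ranking <- ranking[order(ranking$val_rmse), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, per_property = per_prop)
}
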