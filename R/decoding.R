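#' Item-averaged evoked-response container
#'
#' A words x sensors x time-samples array with sampling-rate and epoch-timing
#' metadata. Amplitudes are in fT/cm for real planar-gradiometer data and
#' arbitrary units for synthetic data.
#'
#' @param data Numeric 3-d array (n_words x n_sensors x n_times), all finite.
#' @param sfreq Sampling rate in Hz.
#' @param tmin Time of the first sample relative to stimulus onset, seconds
#'   (negative = pre-stimulus).
#' @param words Character vector of unique word labels, one per row.
#' @return An `epochs_array`.
#' @export
epochs_array <- function(data, sfreq = 1000, tmin = -0.2, words = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("non-finite values in data", call. = FALSE)
  if (is.null(words)) words <- dimnames(data)[[1]]
  if (is.null(words)) words <- paste0("w", seq_len(dim(data)[1]))
  if (length(words) != dim(data)[1] || anyDuplicated(words))
    stop("words must be unique and match dim(data)[1]", call. = FALSE)
  dimnames(data)[[1]] <- words
  structure(list(data = data, sfreq = sfreq, tmin = tmin, words = words),
            class = "epochs_array")
}

#' @export
print.epochs_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs_array: %d words x %d sensors x %d samples, %g Hz, %g..%g s>\n",
              d[1], d[2], d[3], x$sfreq, x$tmin,
              x$tmin + (d[3] - 1) / x$sfreq))
  invisible(x)
}

#' Sample times of an epochs array
#' @param epochs An `epochs_array`.
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$sfreq
}

#' Baseline-correct epochs
#'
#' Subtracts, per word and sensor, the mean amplitude over the pre-stimulus
#' samples (times < 0) from the whole epoch. Idempotent up to numerical
#' noise.
#'
#' @param epochs An `epochs_array` whose epoch includes pre-stimulus samples.
#' @return The baseline-corrected `epochs_array`.
#' @export
apply_baseline <- function(epochs) {
  t <- epoch_times(epochs)
  pre <- which(t < 0)
  if (length(pre) == 0L)
    stop("no pre-stimulus samples to baseline on", call. = FALSE)
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over time (3rd dim)
  epochs
}

#' Reject epochs by peak amplitude
#'
#' Removes words whose peak absolute amplitude strictly exceeds the
#' threshold (default 3000, the fT/cm gradiometer criterion).
#'
#' @param epochs An `epochs_array`.
#' @param threshold Positive rejection threshold.
#' @return List with `epochs` (filtered) and `rejected` (labels removed).
#' @export
reject_epochs <- function(epochs, threshold = 3000) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  peak <- apply(abs(epochs$data), 1, max)
  bad <- peak > threshold
  if (all(bad)) stop("all epochs rejected", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  out$words <- epochs$words[!bad]
  list(epochs = out, rejected = epochs$words[bad])
}

#' Sliding-window specification
#'
#' @param length_ms Window length in milliseconds (default 100).
#' @param step_ms Step between window onsets in milliseconds (default 50,
#'   i.e. 50% overlap); must not exceed `length_ms`.
#' @return A `window_spec`.
#' @export
window_spec <- function(length_ms = 100, step_ms = 50) {
  stopifnot(length_ms > 0, step_ms > 0)
  if (step_ms > length_ms)
    stop("step_ms must not exceed length_ms", call. = FALSE)
  structure(list(length_ms = length_ms, step_ms = step_ms),
            class = "window_spec")
}

#' Cut epochs into overlapping window feature matrices
#'
#' Windows start at epoch onset (`tmin`) and advance by `step_ms` for as
#' long as a full window fits; baseline windows are included so the accuracy
#' time course shows pre-stimulus chance behavior as an internal control.
#' Per window, each word's sensors-by-samples block is flattened
#' sensor-major (sensor index varies fastest) into one feature row.
#'
#' @param epochs An `epochs_array`.
#' @param spec A [window_spec()].
#' @return List of windows, each a list with `center` (seconds), `start`
#'   (first sample index) and `X` (n_words x n_sensors*window_samples).
#' @export
window_slices <- function(epochs, spec = window_spec()) {
  len <- spec$length_ms * epochs$sfreq / 1000
  stp <- spec$step_ms * epochs$sfreq / 1000
  if (abs(len - round(len)) > 1e-9 || abs(stp - round(stp)) > 1e-9)
    stop("window/step must span an integral number of samples", call. = FALSE)
  len <- as.integer(round(len)); stp <- as.integer(round(stp))
  n_times <- dim(epochs$data)[3]
  if (len > n_times) stop("epoch shorter than one window", call. = FALSE)
  starts <- seq.int(1L, n_times - len + 1L, by = stp)
  lapply(starts, function(s) {
    block <- epochs$data[, , s:(s + len - 1L), drop = FALSE]
    X <- matrix(aperm(block, c(2, 3, 1)), nrow = dim(block)[1], byrow = TRUE)
    rownames(X) <- epochs$words
    list(center = epochs$tmin + (s - 1 + (len - 1) / 2) / epochs$sfreq,
         start = s, X = X)
  })
}

#' The standard regularization grid
#'
#' Exactly 100 log-spaced values from 1e-5 to 1e5 inclusive.
#' @return Numeric vector of length 100.
#' @export
default_alpha_grid <- function() 10^seq(-5, 5, length.out = 100)

# Column standardization: center to zero mean, scale to unit sd (n-1
# denominator). Constant columns get scale 1 (flagged via `constant`).
standardize_fit <- function(M) {
  center <- colMeans(M)
  n <- nrow(M)
  sc <- sqrt(colSums(sweep(M, 2, center)^2) / max(n - 1, 1))
  constant <- sc == 0
  sc[constant] <- 1
  list(center = center, scale = sc, constant = constant)
}

standardize_apply <- function(M, par) {
  sweep(sweep(M, 2, par$center), 2, par$scale, "/")
}

# Per-target-dimension alpha selection by exact leave-one-out on the SVD of
# the standardized design (the efficient shortcut; exact for ridge).
# Returns index into alpha_grid for each target dimension.
select_alphas_loo <- function(sv, Ys, alpha_grid) {
  U <- sv$u; d <- sv$d
  UtY <- crossprod(U, Ys)
  U2 <- U^2
  D <- ncol(Ys)
  best_err <- rep(Inf, D)
  best_idx <- rep(1L, D)
  for (g in seq_along(alpha_grid)) {
    s <- d^2 / (d^2 + alpha_grid[g])
    h <- as.vector(U2 %*% s)
    yhat <- U %*% (s * UtY)
    resid <- (Ys - yhat) / (1 - h)
    err <- colMeans(resid^2)
    better <- err < best_err
    best_err[better] <- err[better]
    best_idx[better] <- g
  }
  best_idx
}

# Explicit leave-two-out alpha selection: enumerate all row pairs, refit on
# the rest (fold-internal standardization, like the evaluation folds), and
# accumulate squared prediction error per (alpha, dimension) on the original
# scale.
select_alphas_l2o <- function(X, Y, alpha_grid) {
  n <- nrow(X); D <- ncol(Y)
  err <- matrix(0, length(alpha_grid), D)
  pairs <- combn(n, 2)
  for (p in seq_len(ncol(pairs))) {
    hold <- pairs[, p]
    xs <- standardize_fit(X[-hold, , drop = FALSE])
    ys <- standardize_fit(Y[-hold, , drop = FALSE])
    Xs <- standardize_apply(X[-hold, , drop = FALSE], xs)
    Ys <- standardize_apply(Y[-hold, , drop = FALSE], ys)
    sv <- svd(Xs)
    UtY <- crossprod(sv$u, Ys)
    B <- standardize_apply(X[hold, , drop = FALSE], xs) %*% sv$v   # 2 x r
    for (g in seq_along(alpha_grid)) {
      f <- sv$d / (sv$d^2 + alpha_grid[g])
      pred <- sweep(sweep(B %*% (f * UtY), 2, ys$scale, "*"),
                    2, ys$center, "+")
      err[g, ] <- err[g, ] + colSums((Y[hold, , drop = FALSE] - pred)^2)
    }
  }
  apply(err, 2, which.min)
}

# Ridge coefficients on standardized data from an SVD, one alpha per target
# dimension: beta_j = V diag(d/(d^2+a_j)) U' y_j.
ridge_coef_svd <- function(sv, Ys, alphas) {
  UtY <- crossprod(sv$u, Ys)
  Fm <- outer(sv$d, alphas, function(d, a) d / (d^2 + a))
  sv$v %*% (Fm * UtY)
}

#' Fit ridge regression with per-dimension regularization
#'
#' Columns of `X` and `Y` are standardized to zero mean / unit variance
#' using the supplied (training) rows only; for each target dimension the
#' alpha minimizing cross-validated squared error over the grid is selected
#' independently, and coefficients solve the standardized ridge problem.
#' `cv = "loo"` uses the exact SVD leave-one-out shortcut; `cv = "l2o"`
#' enumerates explicit leave-two-out folds.
#'
#' @param X Feature matrix (n x p), n >= 4.
#' @param Y Target matrix (n x D), row-aligned with `X`.
#' @param alpha_grid Candidate alphas (default: [default_alpha_grid()]).
#' @param alphas Optional fixed per-dimension alphas (length D or 1),
#'   skipping selection.
#' @param cv Alpha-selection scheme, `"loo"` or `"l2o"`.
#' @return A `ridge_map` with coefficients, per-dimension alphas, and the
#'   standardization parameters of both spaces.
#' @export
fit_ridge <- function(X, Y, alpha_grid = default_alpha_grid(),
                      alphas = NULL, cv = c("loo", "l2o")) {
  cv <- match.arg(cv)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned", call. = FALSE)
  if (nrow(X) < 4) stop("need at least 4 rows", call. = FALSE)
  xs <- standardize_fit(X)
  ys <- standardize_fit(Y)
  if (any(xs$constant) || any(ys$constant))
    warning("constant column(s); scale set to 1", call. = FALSE)
  Xs <- standardize_apply(X, xs)
  Ys <- standardize_apply(Y, ys)
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$u <- sv$u[, pos, drop = FALSE]
  sv$v <- sv$v[, pos, drop = FALSE]
  sv$d <- sv$d[pos]
  if (is.null(alphas)) {
    idx <- switch(cv,
      loo = select_alphas_loo(sv, Ys, alpha_grid),
      l2o = select_alphas_l2o(X, Y, alpha_grid))
    alphas <- alpha_grid[idx]
  } else {
    alphas <- rep_len(alphas, ncol(Y))
  }
  structure(list(coef = ridge_coef_svd(sv, Ys, alphas), alphas = alphas,
                 x_standardize = xs, y_standardize = ys,
                 alpha_grid = alpha_grid),
            class = "ridge_map")
}

#' @export
print.ridge_map <- function(x, ...) {
  cat(sprintf("<ridge_map: %d features -> %d dimensions, alpha in [%g, %g]>\n",
              nrow(x$coef), ncol(x$coef), min(x$alphas), max(x$alphas)))
  invisible(x)
}

#' Predict targets from new feature rows
#'
#' Features are standardized with the training parameters; predictions are
#' de-standardized back to the original target scale.
#'
#' @param object A `ridge_map`.
#' @param X_new Feature matrix (rows are items; a single row is accepted).
#' @param ... Unused.
#' @return Prediction matrix in the original target scale.
#' @export
predict.ridge_map <- function(object, X_new, ...) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != nrow(object$coef))
    stop("feature count mismatch", call. = FALSE)
  Xs <- standardize_apply(X_new, object$x_standardize)
  pred <- Xs %*% object$coef
  sweep(sweep(pred, 2, object$y_standardize$scale, "*"),
        2, object$y_standardize$center, "+")
}
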