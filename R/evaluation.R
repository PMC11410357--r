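#' Score one 2-vs-2 comparison
#'
#' The pair is correctly classified (outcome 1) when the matched sum of
#' cosine distances `d(p1,a1) + d(p2,a2)` is strictly smaller than the
#' crossed sum `d(p1,a2) + d(p2,a1)`; outcome 0 when strictly larger; exact
#' ties score 0.5 so accuracy remains an unbiased mean under degenerate
#' predictors.
#'
#' @param p1,p2 Predicted vectors for the two held-out items.
#' @param a1,a2 True vectors for the two held-out items.
#' @return 0, 0.5 or 1.
#' @export
two_vs_two <- function(p1, p2, a1, a2) {
  matched <- cosine_distance(p1, a1) + cosine_distance(p2, a2)
  crossed <- cosine_distance(p1, a2) + cosine_distance(p2, a1)
  if (matched < crossed) 1 else if (matched > crossed) 0 else 0.5
}

# Keep only words present in both the epochs and the (finite rows of the)
# word-vector matrix, preserving epoch order.
align_epochs_vectors <- function(epochs, word_vectors) {
  wv <- as.matrix(word_vectors)
  ok_rows <- rownames(wv)[apply(is.finite(wv), 1, all)]
  words <- intersect(epochs$words, ok_rows)
  dropped <- setdiff(epochs$words, words)
  if (length(dropped))
    warning(length(dropped),
            " word(s) without usable vectors dropped from evaluation",
            call. = FALSE)
  if (length(words) < 4)
    stop("need at least 4 words after alignment", call. = FALSE)
  keep <- match(words, epochs$words)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$words <- words
  list(epochs = out, Y = wv[words, , drop = FALSE], words = words)
}

# Enumerate (or seeded-subsample) unordered word pairs; rows of the returned
# matrix index the aligned word order.
make_pair_index <- function(n, max_pairs = NULL, seed = NULL) {
  pairs <- t(combn(n, 2))
  subsampled <- FALSE
  if (!is.null(max_pairs) && max_pairs < nrow(pairs)) {
    if (is.null(seed))
      stop("pair subsampling requires a seed", call. = FALSE)
    keep <- with_seed(seed, sample.int(nrow(pairs), max_pairs))
    pairs <- pairs[sort(keep), , drop = FALSE]
    subsampled <- TRUE
  }
  attr(pairs, "subsampled") <- subsampled
  pairs
}

# Fit one leave-two-out fold: standardize on training rows, ridge with
# per-dimension alpha (selected by cv when `alphas` is NULL), predict the
# two held-out rows on the original target scale.
fold_predict <- function(X, Y, hold, alpha_grid, alphas = NULL,
                         cv = "loo", standardize = TRUE) {
  train <- setdiff(seq_len(nrow(X)), hold)
  Xtr <- X[train, , drop = FALSE]
  Ytr <- Y[train, , drop = FALSE]
  if (standardize) {
    xs <- standardize_fit(Xtr)
    ys <- standardize_fit(Ytr)
  } else {
    xs <- list(center = numeric(ncol(X)), scale = rep(1, ncol(X)))
    ys <- list(center = numeric(ncol(Y)), scale = rep(1, ncol(Y)))
  }
  Xs <- standardize_apply(Xtr, xs)
  Ys <- standardize_apply(Ytr, ys)
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-12
  sv <- list(u = sv$u[, pos, drop = FALSE], d = sv$d[pos],
             v = sv$v[, pos, drop = FALSE])
  if (is.null(alphas)) {
    idx <- switch(cv,
      loo = select_alphas_loo(sv, Ys, alpha_grid),
      l2o = select_alphas_l2o(Xtr, Ytr, alpha_grid))
    alphas <- alpha_grid[idx]
  } else {
    alphas <- rep_len(alphas, ncol(Y))
  }
  B <- standardize_apply(X[hold, , drop = FALSE], xs) %*% sv$v
  UtY <- crossprod(sv$u, Ys)
  Fm <- outer(sv$d, alphas, function(d, a) d / (d^2 + a))
  pred <- B %*% (Fm * UtY)
  pred <- sweep(sweep(pred, 2, ys$scale, "*"), 2, ys$center, "+")
  list(pred = pred, alphas = alphas)
}

# Evaluate all folds of one window in R (tuning path). Returns per-pair
# outcomes and the per-fold selected alphas (pairs x D).
evaluate_window <- function(X, Y, pair_index, alpha_grid, alphas = NULL,
                            cv = "loo", standardize = TRUE) {
  npairs <- nrow(pair_index)
  outcomes <- numeric(npairs)
  fold_alphas <- matrix(NA_real_, npairs, ncol(Y))
  for (f in seq_len(npairs)) {
    hold <- pair_index[f, ]
    fp <- fold_predict(X, Y, hold, alpha_grid, alphas, cv, standardize)
    fold_alphas[f, ] <- fp$alphas
    outcomes[f] <- two_vs_two(fp$pred[1, ], fp$pred[2, ],
                              Y[hold[1], ], Y[hold[2], ])
  }
  list(outcomes = outcomes, fold_alphas = fold_alphas)
}

# Precompute, per fold, the linear operator mapping standardized training
# targets to the standardized predictions of the two held-out rows, with the
# fold's alphas baked in (array (2, ntr, D)). Only the target side changes
# under either permutation scheme, so scoring a permuted target matrix with
# this cache is exactly full retraining. Fold-internal standardization only.
build_fold_cache <- function(X, pair_index, fold_alphas) {
  n <- nrow(X)
  D <- ncol(fold_alphas)
  folds <- train_idx <- vector("list", nrow(pair_index))
  for (f in seq_len(nrow(pair_index))) {
    hold <- pair_index[f, ]
    train <- setdiff(seq_len(n), hold)
    Xtr <- X[train, , drop = FALSE]
    xs <- standardize_fit(Xtr)
    sv <- svd(standardize_apply(Xtr, xs))
    pos <- sv$d > max(sv$d) * 1e-12
    U <- sv$u[, pos, drop = FALSE]
    d <- sv$d[pos]
    V <- sv$v[, pos, drop = FALSE]
    B <- standardize_apply(X[hold, , drop = FALSE], xs) %*% V  # 2 x r
    tU <- t(U)
    M <- array(0, c(2L, length(train), D))
    for (j in seq_len(D)) {
      g <- d / (d^2 + fold_alphas[f, j])
      M[, , j] <- (B * rep(g, each = 2L)) %*% tU
    }
    folds[[f]] <- M
    train_idx[[f]] <- train
  }
  list(folds = folds, train_idx = train_idx, pair_index = pair_index)
}

# Score a (possibly permuted) target matrix against a fold cache.
eval_cached <- function(cache, Y) {
  .eval_pairs_cached(cache$folds, cache$train_idx,
                     cache$pair_index, as.matrix(Y))
}

#' Run the leave-two-out 2-vs-2 decoding evaluation
#'
#' For each time window and each unordered word pair, a fresh ridge decoder
#' is fitted on the remaining n-2 words (fold-internal standardization,
#' per-dimension alpha tuned within the fold), both held-out words are
#' projected into the semantic space, and the pair is scored with
#' [two_vs_two()]. Window accuracy is the mean outcome over pairs.
#'
#' @param epochs An `epochs_array`.
#' @param word_vectors Word-by-dimension matrix (e.g. from
#'   [compose_word_vectors()]); rows with non-finite values are dropped with
#'   a warning.
#' @param spec A [window_spec()].
#' @param alpha_grid Regularization grid.
#' @param alphas Optional fixed per-dimension alphas (skips tuning).
#' @param cv Alpha-selection scheme, `"loo"` (efficient exact leave-one-out)
#'   or `"l2o"` (explicit leave-two-out).
#' @param max_pairs Optional cap on evaluated pairs (seeded subsample for
#'   desk-scale runs; recorded in the result).
#' @param seed Seed for pair subsampling.
#' @param window_indices Optional subset of window indices to evaluate.
#' @param global_zscore Reproduce global (all-rows) standardization instead
#'   of the default fold-internal standardization, for comparison.
#' @return A `decoding_result`: window centers and accuracies, the per-pair
#'   outcome table, per-fold selected alphas (used by the permutation fast
#'   mode), and a config echo.
#' @export
run_two_vs_two <- function(epochs, word_vectors, spec = window_spec(),
                           alpha_grid = default_alpha_grid(), alphas = NULL,
                           cv = c("loo", "l2o"), max_pairs = NULL,
                           seed = NULL, window_indices = NULL,
                           global_zscore = FALSE) {
  cv <- match.arg(cv)
  al <- align_epochs_vectors(epochs, word_vectors)
  slices <- window_slices(al$epochs, spec)
  if (is.null(window_indices)) window_indices <- seq_along(slices)
  slices <- slices[window_indices]
  n <- length(al$words)
  pair_index <- make_pair_index(n, max_pairs, seed)
  Y <- al$Y
  standardize <- !global_zscore
  if (global_zscore) {
    Y <- standardize_apply(Y, standardize_fit(Y))
  }
  centers <- vapply(slices, `[[`, 0, "center")
  accuracy <- numeric(length(slices))
  fold_alphas <- vector("list", length(slices))
  pair_rows <- vector("list", length(slices))
  for (w in seq_along(slices)) {
    X <- slices[[w]]$X
    if (global_zscore) X <- standardize_apply(X, standardize_fit(X))
    ev <- evaluate_window(X, Y, pair_index, alpha_grid, alphas, cv,
                          standardize)
    accuracy[w] <- mean(ev$outcomes)
    fold_alphas[[w]] <- ev$fold_alphas
    pair_rows[[w]] <- data.frame(
      word_i = al$words[pair_index[, 1]],
      word_j = al$words[pair_index[, 2]],
      window_center_s = centers[w],
      outcome = ev$outcomes)
  }
  structure(list(
    window_centers = centers,
    accuracy = accuracy,
    pairs = do.call(rbind, pair_rows),
    n_pairs = nrow(pair_index),
    pair_index = pair_index,
    subsampled = isTRUE(attr(pair_index, "subsampled")),
    words = al$words,
    fold_alphas = fold_alphas,
    config = list(spec = spec, cv = cv, alphas = alphas,
                  max_pairs = max_pairs, seed = seed,
                  window_indices = window_indices,
                  global_zscore = global_zscore,
                  alpha_grid_range = range(alpha_grid),
                  alpha_grid_points = length(alpha_grid))),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result: %d windows, %d words, %d pairs%s>\n",
              length(x$accuracy), length(x$words), x$n_pairs,
              if (x$subsampled) " (subsampled)" else ""))
  cat(sprintf("  peak accuracy %.3f at %g s\n", max(x$accuracy),
              x$window_centers[which.max(x$accuracy)]))
  invisible(x)
}

#' Accuracy as a function of time
#'
#' @param result A `decoding_result`.
#' @return Data frame with `window_center_s`, `accuracy`, `n_pairs`, ordered
#'   by time; ready for plotting or overlay with permutation thresholds.
#' @export
accuracy_timecourse <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  out <- data.frame(window_center_s = result$window_centers,
                    accuracy = result$accuracy,
                    n_pairs = result$n_pairs)
  out[order(out$window_center_s), , drop = FALSE]
}

#' Index of the best-decoding window
#' @param result A `decoding_result`.
#' @return Integer index (into the evaluated windows) of peak accuracy.
#' @export
peak_window <- function(result) which.max(result$accuracy)
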