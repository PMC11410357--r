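new_permutation_result <- function(kind, null, observed, seed, level,
                                   quantile_method, window_center) {
  td <- threshold_and_decide(observed, null, level, quantile_method)
  structure(list(kind = kind, null = null, observed = observed,
                 threshold = td$threshold, p = td$p,
                 significant = td$significant, margin = td$margin,
                 n_perm = length(null), level = level,
                 quantile_method = quantile_method, seed = seed,
                 window_center = window_center),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: %s, %d permutations>\n", x$kind, x$n_perm))
  cat(sprintf("  observed %.3f vs threshold %.3f (%.0fth pct) -> %s, p = %.4g\n",
              x$observed, x$threshold, 100 * x$level,
              if (x$significant) "significant" else "not significant", x$p))
  invisible(x)
}

#' Compare an observed accuracy against a permutation null
#'
#' The significance threshold is the `level` quantile of the null accuracy
#' distribution (linear-interpolation quantile by default; `"nearest"` uses
#' the nearest-rank convention). The empirical p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param observed Observed accuracy.
#' @param null Numeric vector of null accuracies.
#' @param level Quantile level (default 0.95).
#' @param quantile_method `"linear"` or `"nearest"`.
#' @return List with `threshold`, `significant` (`observed > threshold`),
#'   `margin` (`observed - threshold`) and `p`.
#' @export
threshold_and_decide <- function(observed, null, level = 0.95,
                                 quantile_method = c("linear", "nearest")) {
  quantile_method <- match.arg(quantile_method)
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  threshold <- unname(quantile(null, level,
                               type = if (quantile_method == "linear") 7 else 1))
  list(threshold = threshold,
       significant = observed > threshold,
       margin = observed - threshold,
       p = (1 + sum(null >= observed)) / (1 + length(null)))
}

# Shared machinery: observed tuned run at one window, then a fold cache with
# the observed-run per-fold alphas. Scoring a permuted target matrix against
# the cache is exact full retraining (only the target side of each fold
# changes under either permutation kind).
null_setup <- function(epochs, word_vectors, window, spec, alpha_grid, cv,
                       max_pairs, seed) {
  al <- align_epochs_vectors(epochs, word_vectors)
  slices <- window_slices(al$epochs, spec)
  if (window < 1 || window > length(slices))
    stop("window index out of range (", length(slices), " windows)",
         call. = FALSE)
  X <- slices[[window]]$X
  pair_index <- make_pair_index(length(al$words), max_pairs, seed)
  obs <- evaluate_window(X, al$Y, pair_index, alpha_grid, NULL, cv, TRUE)
  list(X = X, Y = al$Y, words = al$words, pair_index = pair_index,
       observed = mean(obs$outcomes),
       cache = build_fold_cache(X, pair_index, obs$fold_alphas),
       center = slices[[window]]$center)
}

#' Word-label permutation null
#'
#' The standard chance estimate: for each permutation the assignment between
#' brain-response rows and word-vector rows is shuffled uniformly at random
#' and the full 2-vs-2 evaluation is re-run at the given window. The
#' significance threshold is the 95th percentile of the null accuracies.
#'
#' By default each permutation reuses the per-fold alphas selected in the
#' observed run (fast mode; the sensor-side fold computations are unchanged
#' by the permutation, so this is exact retraining at fixed alphas). Set
#' `retune_alphas = TRUE` to re-tune alphas inside every permutation fold.
#'
#' @param epochs An `epochs_array`.
#' @param word_vectors Word-by-dimension matrix.
#' @param window Index of the time window to test (see [window_slices()]).
#' @param spec A [window_spec()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed controlling both pair subsampling and the permutations.
#' @param max_pairs Optional seeded pair subsampling.
#' @param alpha_grid,cv Ridge tuning options as in [run_two_vs_two()].
#' @param retune_alphas Re-tune alphas within every permutation (slow).
#' @param level,quantile_method Passed to [threshold_and_decide()].
#' @return A `permutation_result` (kind `"word_label"`).
#' @export
word_label_null <- function(epochs, word_vectors, window,
                            spec = window_spec(), n_perm = 1000, seed = 1,
                            max_pairs = NULL,
                            alpha_grid = default_alpha_grid(),
                            cv = c("loo", "l2o"), retune_alphas = FALSE,
                            level = 0.95,
                            quantile_method = c("linear", "nearest")) {
  cv <- match.arg(cv)
  quantile_method <- match.arg(quantile_method)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  st <- null_setup(epochs, word_vectors, window, spec, alpha_grid, cv,
                   max_pairs, seed)
  n <- length(st$words)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    Yp <- st$Y[sample.int(n), , drop = FALSE]
    if (retune_alphas) {
      mean(evaluate_window(st$X, Yp, st$pair_index, alpha_grid, NULL, cv,
                           TRUE)$outcomes)
    } else {
      mean(eval_cached(st$cache, Yp))
    }
  }, 0))
  new_permutation_result("word_label", null, st$observed, seed, level,
                         quantile_method, st$center)
}

#' Shuffle the pairing between segment labels and segment vectors
#'
#' Draws a uniform random bijection (identity included) on the given segment
#' set, so each label becomes associated with a randomly selected vector
#' from that set; the multiset of vectors is preserved exactly and segments
#' outside the set are untouched. Words sharing a segment before the shuffle
#' still share one vector term after it — the shared-segment structure of
#' composed word vectors survives, which is exactly what this null isolates.
#'
#' @param store A `segment_vector_store`.
#' @param segments Character vector of at least two segment labels to
#'   shuffle among (typically the segment types of the stimulus words).
#' @param seed Optional seed.
#' @return The permuted `segment_vector_store`.
#' @export
permute_segment_store <- function(store, segments, seed = NULL) {
  segments <- unique(segments)
  if (!all(segments %in% rownames(store$vectors)))
    stop("segments absent from store", call. = FALSE)
  if (length(segments) < 2)
    stop("need at least 2 segments to permute", call. = FALSE)
  perm <- with_seed(seed, sample.int(length(segments)))
  orig <- store$vectors[segments, , drop = FALSE]
  store$vectors[segments, ] <- orig[perm, , drop = FALSE]
  store
}

#' Segment-label permutation null
#'
#' The critical test for compositional decoding: for each permutation the
#' bijection between segment labels and segment vectors is reshuffled over
#' the segment types of the words under study, all word vectors are
#' recomposed by summation, and the full 2-vs-2 evaluation is re-run. The
#' word-by-segment occurrence pattern (hence all shared-segment structure)
#' is identical in every permutation; only the identity of the segment
#' vectors is scrambled. A threshold far above the word-label threshold
#' means decoding can succeed from shared-segment structure alone.
#'
#' @param epochs An `epochs_array`.
#' @param lexicon A `segmented_lexicon` covering the stimulus words.
#' @param store A `segment_vector_store`.
#' @param window Index of the time window to test.
#' @param spec,n_perm,seed,max_pairs,alpha_grid,cv,retune_alphas,level,quantile_method
#'   As in [word_label_null()].
#' @param words Words under study (default: all epoch words in the lexicon).
#' @param segments Segment set to permute (default: the segment types of
#'   `words` that have store vectors).
#' @return A `permutation_result` (kind `"segment_label"`).
#' @export
segment_label_null <- function(epochs, lexicon, store, window,
                               spec = window_spec(), n_perm = 1000, seed = 1,
                               words = NULL, segments = NULL,
                               max_pairs = NULL,
                               alpha_grid = default_alpha_grid(),
                               cv = c("loo", "l2o"), retune_alphas = FALSE,
                               level = 0.95,
                               quantile_method = c("linear", "nearest")) {
  cv <- match.arg(cv)
  quantile_method <- match.arg(quantile_method)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(words))
    words <- intersect(epochs$words, names(lexicon$entries))
  wv <- suppressWarnings(compose_word_vectors(lexicon, store, words))
  st <- null_setup(epochs, wv, window, spec, alpha_grid, cv, max_pairs, seed)

  if (is.null(segments)) {
    segments <- unique(unlist(lexicon$entries[st$words], use.names = FALSE))
    segments <- intersect(segments, rownames(store$vectors))
  }
  if (length(segments) < 2)
    stop("need at least 2 stimulus segments to permute", call. = FALSE)

  # Composition is linear in the store, so each permutation is a fixed
  # occurrence-count matrix times a row permutation of the stimulus-segment
  # vectors (plus the fixed contribution of any covered non-stimulus
  # segments). Identical to composing from the permuted store.
  Vstim <- store$vectors[segments, , drop = FALSE]
  S <- matrix(0, length(st$words), length(segments),
              dimnames = list(st$words, segments))
  base <- matrix(0, length(st$words), store$dim)
  for (i in seq_along(st$words)) {
    segs <- lexicon$entries[[st$words[i]]]
    covered <- segs[segs %in% rownames(store$vectors)]
    in_set <- covered[covered %in% segments]
    if (length(in_set)) {
      tab <- table(in_set)
      S[i, names(tab)] <- as.integer(tab)
    }
    out_set <- covered[!covered %in% segments]
    if (length(out_set))
      base[i, ] <- colSums(store$vectors[out_set, , drop = FALSE])
  }

  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(length(segments))
    Yp <- base + S %*% Vstim[perm, , drop = FALSE]
    if (retune_alphas) {
      mean(evaluate_window(st$X, Yp, st$pair_index, alpha_grid, NULL, cv,
                           TRUE)$outcomes)
    } else {
      mean(eval_cached(st$cache, Yp))
    }
  }, 0))
  new_permutation_result("segment_label", null, st$observed, seed, level,
                         quantile_method, st$center)
}
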