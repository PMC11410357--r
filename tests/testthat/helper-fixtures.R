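# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, closed forms) and share no code with the package paths
# they check.

# Small synthetic study used across tests: 20 words, 6 sensors at 100 Hz so
# a 100-ms window holds 10 samples (60 features), strong signal.
tiny_config <- function(snr = 5, seed = 7, ...) {
  synthetic_config(n_stems = 10, n_suffixes = 2, dim = 8, n_sensors = 6,
                   sfreq = 100, snr = snr, semantic_clusters = 3,
                   seed = seed, ...)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(tiny_config())
    cache
  }
})

# Closed-form ridge on already-standardized data: (X'X + aI)^{-1} X'y.
ridge_closed_form <- function(Xs, Ys, alphas) {
  p <- ncol(Xs)
  sapply(seq_len(ncol(Ys)), function(j) {
    solve(crossprod(Xs) + alphas[j] * diag(p), crossprod(Xs, Ys[, j]))
  })
}

# Naive cosine distance.
naive_cos <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Naive leave-two-out 2v2 at a single window with fixed alphas: explicit
# loops, standardization and ridge solve written out longhand.
naive_two_vs_two_run <- function(X, Y, alpha) {
  n <- nrow(X)
  pairs <- t(combn(n, 2))
  outcomes <- numeric(nrow(pairs))
  for (f in seq_len(nrow(pairs))) {
    hold <- pairs[f, ]
    tr <- setdiff(1:n, hold)
    xm <- colMeans(X[tr, , drop = FALSE])
    xs <- apply(X[tr, , drop = FALSE], 2, sd); xs[xs == 0] <- 1
    ym <- colMeans(Y[tr, , drop = FALSE])
    ys <- apply(Y[tr, , drop = FALSE], 2, sd); ys[ys == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, xm), 2, xs, "/")
    Ytr <- sweep(sweep(Y[tr, , drop = FALSE], 2, ym), 2, ys, "/")
    Xte <- sweep(sweep(X[hold, , drop = FALSE], 2, xm), 2, xs, "/")
    B <- solve(crossprod(Xtr) + alpha * diag(ncol(Xtr)), crossprod(Xtr, Ytr))
    pred <- sweep(sweep(Xte %*% B, 2, ys, "*"), 2, ym, "+")
    m <- naive_cos(pred[1, ], Y[hold[1], ]) + naive_cos(pred[2, ], Y[hold[2], ])
    x <- naive_cos(pred[1, ], Y[hold[2], ]) + naive_cos(pred[2, ], Y[hold[1], ])
    outcomes[f] <- if (m < x) 1 else if (m > x) 0 else 0.5
  }
  list(pairs = pairs, outcomes = outcomes)
}

# O(n^3) naive complete-linkage agglomeration over a distance matrix;
# returns the sorted sequence of merge heights.
naive_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dist_ij <- max(d[clusters[[i]], clusters[[j]]])
        if (dist_ij < best[1]) best <- c(dist_ij, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
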