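#' Configuration for the synthetic multimorphemic study
#'
#' Defines the conditions of a simulated decoding experiment: an artificial
#' agglutinative lexicon (unique stems carrying cluster semantics, a small
#' closed suffix set shared by many words), structured segment vectors, and
#' evoked responses that are a noisy linear projection of the composed word
#' vectors inside a restricted post-stimulus effect window. Epoch timing
#' (-200..800 ms), sensor count (204 planar gradiometers), sampling rate
#' (1000 Hz) and the 350-500 ms effect window default to the real-study
#' geometry; desk-scale analyses override them explicitly.
#'
#' @param n_stems Number of stems (each used by several words; stems are the
#'   rare, semantically loaded segments).
#' @param n_suffixes Size of the closed suffix set (each suffix is shared by
#'   many words — the shared-segment structure the segment-label permutation
#'   test is about).
#' @param suffixes_per_word 1 or 2 suffix slots per word.
#' @param n_words Optional cap on the number of generated words (sampled
#'   from the stem-by-suffix combinations); default: all combinations.
#' @param dim Embedding dimension D.
#' @param n_sensors Number of sensors.
#' @param sfreq Sampling rate, Hz.
#' @param tmin,tmax Epoch span, seconds.
#' @param effect_window Two-element vector, seconds; the interval carrying
#'   stimulus information.
#' @param snr Signal-to-noise ratio: RMS of the projected signal over the
#'   effect window divided by noise RMS (noise has unit RMS). `0` = pure
#'   noise.
#' @param semantic_clusters Number of stem-semantics clusters.
#' @param stem_len,suffix_len Length ranges (code points) for generated
#'   stems and suffixes; defaults give word lengths of roughly 5-11.
#' @param ar_rho AR(1) coefficient for temporally correlated noise
#'   (default 0 = white).
#' @param seed Master seed; all generation is deterministic given the
#'   config.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_stems = 20, n_suffixes = 4,
                             suffixes_per_word = 1, n_words = NULL,
                             dim = 20, n_sensors = 204, sfreq = 1000,
                             tmin = -0.2, tmax = 0.8,
                             effect_window = c(0.35, 0.50), snr = 1,
                             semantic_clusters = 4,
                             stem_len = c(4, 8), suffix_len = c(1, 3),
                             ar_rho = 0, seed = 1L) {
  stopifnot(n_stems >= 1, n_suffixes >= 1, suffixes_per_word %in% 1:2,
            dim >= 1, n_sensors >= 1, sfreq > 0, tmax > tmin,
            length(effect_window) == 2, snr >= 0,
            semantic_clusters >= 1, dim >= semantic_clusters,
            ar_rho >= 0, ar_rho < 1)
  if (effect_window[1] < tmin || effect_window[2] > tmax ||
      effect_window[1] >= effect_window[2])
    stop("effect window must lie within the epoch", call. = FALSE)
  n_combos <- n_stems * if (suffixes_per_word == 1) n_suffixes else
    n_suffixes * (n_suffixes - 1)
  n_req <- if (is.null(n_words)) n_combos else n_words
  if (n_req > n_combos)
    stop("requested words exceed unique stem-suffix combinations",
         call. = FALSE)
  if (n_req < 4)
    stop("need at least 4 words", call. = FALSE)
  structure(list(n_stems = n_stems, n_suffixes = n_suffixes,
                 suffixes_per_word = suffixes_per_word, n_words = n_words,
                 dim = dim, n_sensors = n_sensors, sfreq = sfreq,
                 tmin = tmin, tmax = tmax, effect_window = effect_window,
                 snr = snr, semantic_clusters = semantic_clusters,
                 stem_len = stem_len, suffix_len = suffix_len,
                 ar_rho = ar_rho, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Finnish-flavoured letter inventories; multibyte vowels exercise the
# code-point length convention. Stems and suffixes draw from disjoint
# inventories (mirroring the disjoint vector subspaces) so that character
# sharing between words tracks shared morphology, the regime the
# segment-permutation argument concerns: in real agglutinative text, words
# sharing several characters are, on average, more likely to share a suffix.
stem_alphabet <- c("a", "o", "u", "ä", "ö", "k", "l", "m", "p", "r", "v", "h")
suffix_alphabet <- c("e", "i", "n", "t", "s", "j")

random_string <- function(alphabet, len_range, n) {
  vapply(seq_len(n), function(i) {
    l <- sample(len_range[1]:len_range[2], 1)
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, "")
}

unique_strings <- function(alphabet, len_range, n) {
  out <- character(0)
  for (tries in 1:200) {
    out <- unique(c(out, random_string(alphabet, len_range, n)))
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("could not generate enough unique strings", call. = FALSE)
}

#' Generate an artificial multimorphemic lexicon
#'
#' Words are `stem + suffix` (or `stem + suffix1 + suffix2`) with stems
#' drawn long enough to be unique and suffixes short and shared: every
#' suffix occurs in many words while every stem is rare, reproducing the
#' shared-segment structure the segment-label permutation argument hinges
#' on. Stems and suffixes draw from disjoint letter inventories, so
#' character sharing between words tracks shared morphology. The true
#' morphological segmentation is recorded; each stem is assigned to one of
#' `semantic_clusters` meaning clusters (round robin).
#'
#' @param config A [synthetic_config()].
#' @return List with `lexicon` (the ground-truth `segmented_lexicon`),
#'   `words`, `stems`, `suffixes` and `stem_cluster` (named integer vector).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    for (attempt in 1:50) {
      stems <- unique_strings(stem_alphabet, config$stem_len, config$n_stems)
      suffixes <- unique_strings(suffix_alphabet, config$suffix_len,
                                 config$n_suffixes)
      combos <- if (config$suffixes_per_word == 1) {
        expand.grid(stem = stems, s1 = suffixes, stringsAsFactors = FALSE)
      } else {
        g <- expand.grid(stem = stems, s1 = suffixes, s2 = suffixes,
                         stringsAsFactors = FALSE)
        g[g$s1 != g$s2, , drop = FALSE]
      }
      if (!is.null(config$n_words))
        combos <- combos[sample.int(nrow(combos), config$n_words), ,
                         drop = FALSE]
      segs <- lapply(seq_len(nrow(combos)),
                     function(i) unlist(combos[i, ], use.names = FALSE))
      words <- vapply(segs, paste, "", collapse = "")
      if (!anyDuplicated(words) && !any(words %in% c(stems, suffixes)))
        break
    }
    if (anyDuplicated(words))
      stop("could not generate a collision-free lexicon", call. = FALSE)
    names(segs) <- words
    scheme <- structure(list(name = "lexicon", source_path = "synthetic-truth"),
                        class = "segmentation_scheme")
    cluster <- rep_len(seq_len(config$semantic_clusters), length(stems))
    names(cluster) <- stems
    list(lexicon = new_segmented_lexicon(segs, scheme), words = words,
         stems = stems, suffixes = suffixes, stem_cluster = cluster)
  })
}

#' Generate structured segment vectors
#'
#' Emulates the distributional structure skip-gram training would learn:
#' stem vectors are isotropic noise around one of the cluster centroids in a
#' stem subspace (cluster semantics), suffix vectors live in a disjoint
#' subspace with smaller norm (shared grammatical directions, orthogonal in
#' expectation to the stem centroids).
#'
#' @param lex Output of [generate_lexicon()].
#' @param config The same [synthetic_config()].
#' @return A `segment_vector_store` over all stems and suffixes.
#' @export
generate_segment_vectors <- function(lex, config) {
  D <- config$dim
  n_suffix_dims <- max(1L, min(D - config$semantic_clusters, D %/% 5L))
  stem_dims <- seq_len(D - n_suffix_dims)
  suffix_dims <- (D - n_suffix_dims + 1L):D
  with_seed(config$seed + 1L, {
    centroids <- matrix(rnorm(config$semantic_clusters * length(stem_dims)),
                        config$semantic_clusters)
    V <- matrix(0, length(lex$stems) + length(lex$suffixes), D,
                dimnames = list(c(lex$stems, lex$suffixes), NULL))
    for (i in seq_along(lex$stems)) {
      cl <- lex$stem_cluster[[lex$stems[i]]]
      V[i, stem_dims] <- centroids[cl, ] + 0.4 * rnorm(length(stem_dims))
    }
    for (j in seq_along(lex$suffixes)) {
      V[length(lex$stems) + j, suffix_dims] <- 0.5 * rnorm(length(suffix_dims))
    }
    segment_vector_store(V)
  })
}

#' Generate a toy segmented-training corpus
#'
#' Emits whitespace-tokenized UTF-8 sentences in which words from the same
#' semantic cluster share cluster-specific filler contexts (so that
#' distributional training recovers the cluster structure), with every
#' stimulus word — hence every stimulus segment — reaching `min_freq`
#' occurrences. With `exclude_targets = TRUE` no sentence contains any
#' stimulus surface form: stems and suffixes appear as free tokens instead,
#' emulating the out-of-vocabulary regime where word vectors must be
#' composed from segments learned elsewhere.
#'
#' @param lex Output of [generate_lexicon()].
#' @param config The same [synthetic_config()].
#' @param min_freq Minimum occurrences per stimulus word (and therefore per
#'   segment).
#' @param exclude_targets Emit the out-of-vocabulary corpus variant.
#' @return Character vector, one sentence per element.
#' @export
generate_corpus <- function(lex, config, min_freq = 50,
                            exclude_targets = FALSE) {
  fillers <- lapply(seq_len(config$semantic_clusters), function(cl)
    paste0("ctx", cl, c("x", "y", "z")))
  with_seed(config$seed + 2L, {
    sentences <- character(0)
    for (rep in seq_len(min_freq)) {
      for (w in sample(lex$words)) {
        segs <- lex$lexicon$entries[[w]]
        cl <- lex$stem_cluster[[segs[1]]]
        ctx <- sample(fillers[[cl]], 3, replace = TRUE)
        core <- if (exclude_targets) segs else w
        sentences <- c(sentences,
                       paste(c(ctx[1], core, ctx[2:3]), collapse = " "))
      }
    }
    sample(sentences)
  })
}

raised_cosine_envelope <- function(times, window) {
  inside <- times >= window[1] & times <= window[2]
  env <- numeric(length(times))
  env[inside] <- 0.5 * (1 - cos(2 * pi * (times[inside] - window[1]) /
                                  (window[2] - window[1])))
  env
}

#' Simulate item-averaged evoked responses
#'
#' Each word's response is a random linear sensor projection of its composed
#' word vector, gated by a raised-cosine temporal envelope supported on the
#' effect window, plus Gaussian noise (optionally AR(1) along time):
#' `data[w,s,t] = gain * env(t) * (M v_w)[s] + noise`. The gain is set so
#' the signal RMS over the effect window equals `snr` times the noise RMS;
#' pre-stimulus and early windows are signal-free by construction.
#'
#' @param word_vectors Word-by-dimension matrix (finite rows only).
#' @param config A [synthetic_config()].
#' @param mixing Optional sensors-by-D mixing matrix (default: random
#'   Gaussian, drawn under the config seed).
#' @return List with `epochs` (an `epochs_array`) and `truth` (mixing
#'   matrix, envelope samples, gain, effect window, envelope shape).
#' @export
simulate_epochs <- function(word_vectors, config, mixing = NULL) {
  if (config$snr < 0) stop("snr must be >= 0", call. = FALSE)
  wv <- as.matrix(word_vectors)
  if (!all(is.finite(wv))) stop("non-finite word vectors", call. = FALSE)
  n_times <- round((config$tmax - config$tmin) * config$sfreq)
  times <- config$tmin + (seq_len(n_times) - 1) / config$sfreq
  env <- raised_cosine_envelope(times, config$effect_window)
  n_words <- nrow(wv)
  with_seed(config$seed + 3L, {
    if (is.null(mixing))
      mixing <- matrix(rnorm(config$n_sensors * ncol(wv)),
                       config$n_sensors) / sqrt(ncol(wv))
    proj <- wv %*% t(mixing)                      # words x sensors
    signal <- outer(proj, env)                    # words x sensors x times
    eff <- which(env > 0)
    gain <- if (config$snr > 0) {
      rms <- sqrt(mean(signal[, , eff]^2))
      if (rms == 0) stop("degenerate signal (all-zero projection)",
                         call. = FALSE)
      config$snr / rms
    } else 0
    noise <- array(rnorm(n_words * config$n_sensors * n_times),
                   c(n_words, config$n_sensors, n_times))
    if (config$ar_rho > 0) {
      r <- config$ar_rho
      for (t in 2:n_times)
        noise[, , t] <- r * noise[, , t - 1] +
          sqrt(1 - r^2) * noise[, , t]
    }
    data <- gain * signal + noise
    list(epochs = epochs_array(data, sfreq = config$sfreq,
                               tmin = config$tmin, words = rownames(wv)),
         truth = list(mixing = mixing, envelope = env, gain = gain,
                      effect_window = config$effect_window,
                      envelope_shape = "raised_cosine"))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs lexicon, segment-vector, composition and epoch simulation in
#' sequence under the config seed. Identical config gives a bit-identical
#' dataset.
#'
#' @param config A [synthetic_config()].
#' @return List with `config`, `lexicon`, `words`, `stems`, `suffixes`,
#'   `store`, `word_vectors`, `epochs` and `truth`.
#' @export
generate_dataset <- function(config) {
  lex <- generate_lexicon(config)
  store <- generate_segment_vectors(lex, config)
  wv <- compose_word_vectors(lex$lexicon, store, lex$words)
  sim <- simulate_epochs(wv, config)
  list(config = config, lexicon = lex$lexicon, words = lex$words,
       stems = lex$stems, suffixes = lex$suffixes,
       stem_cluster = lex$stem_cluster, store = store,
       word_vectors = wv, epochs = sim$epochs, truth = sim$truth)
}

#' Indices of windows fully inside (or fully before) the effect window
#'
#' Convenience for picking the test window of permutation runs and the
#' pre-stimulus control windows.
#'
#' @param epochs An `epochs_array`.
#' @param spec A [window_spec()].
#' @param effect_window Two-element vector, seconds.
#' @return List with `effect` (windows overlapping the effect interval) and
#'   `pre` (windows entirely before stimulus onset).
#' @export
effect_window_indices <- function(epochs, spec, effect_window) {
  slices <- window_slices(epochs, spec)
  half <- spec$length_ms / 2000
  centers <- vapply(slices, `[[`, 0, "center")
  list(effect = which(centers - half < effect_window[2] &
                        centers + half > effect_window[1]),
       pre = which(centers + half <= 0))
}
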