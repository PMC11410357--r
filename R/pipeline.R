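#' Configuration for an end-to-end pipeline run
#'
#' One flat configuration object drives the full analysis: synthetic-data
#' conditions, the segmentation schemes to compare, window geometry,
#' decoder options and permutation options. Every random operation derives
#' its seed from `synthetic$seed`.
#'
#' @param synthetic A [synthetic_config()].
#' @param schemes Named list of [segmentation_scheme()]s to compare; the
#'   special name `"morph"` uses the ground-truth morphological lexicon.
#' @param spec A [window_spec()].
#' @param n_perm Permutations per null distribution.
#' @param max_pairs Optional seeded pair subsampling for desk-scale runs.
#' @param segment_vectors `"truth"`: the morphological scheme uses the
#'   generated ground-truth store and other schemes use random Gaussian
#'   stores over their segment types (isolates composition structure from
#'   training noise); `"train"`: skip-gram vectors are trained on the
#'   generated corpus under each scheme.
#' @param embedding An [embedding_config()] (used when
#'   `segment_vectors="train"`).
#' @param min_freq Corpus frequency floor used when generating the training
#'   corpus.
#' @param level Significance level for permutation thresholds.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            schemes = list(
                              morph = segmentation_scheme("whole"),
                              ngram1 = segmentation_scheme("ngram", k = 1),
                              random = segmentation_scheme("random",
                                                           seed = 99L)),
                            spec = window_spec(),
                            n_perm = 1000, max_pairs = NULL,
                            segment_vectors = c("truth", "train"),
                            embedding = NULL, min_freq = 50, level = 0.95) {
  segment_vectors <- match.arg(segment_vectors)
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(spec, "window_spec"), n_perm >= 1)
  if (is.null(names(schemes)) || any(!nzchar(names(schemes))))
    stop("schemes must be a named list", call. = FALSE)
  structure(list(synthetic = synthetic, schemes = schemes, spec = spec,
                 n_perm = n_perm, max_pairs = max_pairs,
                 segment_vectors = segment_vectors, embedding = embedding,
                 min_freq = min_freq, level = level),
            class = "pipeline_config")
}

# A random Gaussian store over given segment labels: composition then
# carries only shared-segment structure, no per-segment information.
random_segment_store <- function(labels, dim, seed) {
  with_seed(seed, {
    V <- matrix(rnorm(length(labels) * dim), length(labels),
                dimnames = list(labels, NULL))
    segment_vector_store(V)
  })
}

scheme_lexicon_store <- function(name, scheme, ds, config) {
  words <- ds$words
  if (name == "morph") {
    lexicon <- ds$lexicon
    store <- if (config$segment_vectors == "truth") ds$store else NULL
  } else {
    lexicon <- build_segmented_lexicon(words, scheme)
    store <- NULL
  }
  if (is.null(store)) {
    segs <- unique(unlist(lexicon$entries, use.names = FALSE))
    if (config$segment_vectors == "train") {
      corpus <- generate_corpus(list(lexicon = ds$lexicon, words = ds$words,
                                     stems = ds$stems,
                                     suffixes = ds$suffixes,
                                     stem_cluster = ds$stem_cluster),
                                config$synthetic, min_freq = config$min_freq)
      emb <- config$embedding
      if (is.null(emb))
        emb <- embedding_config(dim = config$synthetic$dim,
                                min_count = config$min_freq,
                                seed = config$synthetic$seed)
      store <- train_segment_vectors(corpus, emb, lexicon = lexicon)
    } else {
      store <- random_segment_store(
        segs, config$synthetic$dim,
        config$synthetic$seed + 100L + utf8ToInt(substr(name, 1, 1)))
    }
  }
  list(lexicon = lexicon, store = store)
}

#' Run the full pipeline on synthetic data
#'
#' Generates a dataset, then for every scheme: builds the segmentation,
#' obtains segment vectors, composes word vectors, runs the windowed 2-vs-2
#' evaluation, and computes the word-label and segment-label permutation
#' nulls at the effect window. Results are returned, and written to
#' `out_dir` (per-scheme accuracy TSVs, a comparison summary JSON stamped
#' with the config hash and seed, lexicon TSVs and a dendrogram) when
#' `out_dir` is given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A `pipeline_result`: per-scheme decoding results, permutation
#'   results, and the comparison table (observed accuracy vs word-label vs
#'   segment-label thresholds per scheme).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$synthetic$seed
  ds <- generate_dataset(config$synthetic)
  win <- effect_window_indices(ds$epochs, config$spec,
                               config$synthetic$effect_window)
  test_window <- win$effect[ceiling(length(win$effect) / 2)]
  schemes <- names(config$schemes)
  runs <- list()
  for (name in schemes) {
    ls <- scheme_lexicon_store(name, config$schemes[[name]], ds, config)
    wv <- suppressWarnings(
      compose_word_vectors(ls$lexicon, ls$store, ds$words))
    result <- run_two_vs_two(ds$epochs, wv, config$spec,
                             max_pairs = config$max_pairs, seed = seed)
    wl <- word_label_null(ds$epochs, wv, window = test_window,
                          spec = config$spec, n_perm = config$n_perm,
                          seed = seed + 1L, max_pairs = config$max_pairs,
                          level = config$level)
    sl <- if (all(lengths(ls$lexicon$entries) == 1L)) {
      NULL  # whole-word model: no segment-label permutation exists
    } else {
      segment_label_null(ds$epochs, ls$lexicon, ls$store,
                         window = test_window, spec = config$spec,
                         n_perm = config$n_perm, seed = seed + 2L,
                         words = ds$words, max_pairs = config$max_pairs,
                         level = config$level)
    }
    runs[[name]] <- list(lexicon = ls$lexicon, store = ls$store,
                         word_vectors = wv, result = result,
                         word_label = wl, segment_label = sl)
  }
  comparison <- data.frame(
    scheme = schemes,
    observed_accuracy = vapply(runs, function(r) r$word_label$observed, 0),
    word_label_threshold = vapply(runs, function(r) r$word_label$threshold, 0),
    segment_label_threshold = vapply(runs, function(r)
      if (is.null(r$segment_label)) NA_real_ else r$segment_label$threshold, 0),
    row.names = NULL)
  comparison$significant_vs_word <-
    comparison$observed_accuracy > comparison$word_label_threshold
  comparison$significant_vs_segment <-
    comparison$observed_accuracy > comparison$segment_label_threshold

  out <- structure(list(config = config, dataset = ds, runs = runs,
                        comparison = comparison,
                        test_window = test_window,
                        test_window_center =
                          runs[[1]]$word_label$window_center),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result: ", nrow(x$comparison), " scheme(s), test window ",
      x$test_window_center, " s>\n", sep = "")
  print(x$comparison)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  hash <- config_hash(cfg)
  meta <- c(config_hash = hash, seed = cfg$synthetic$seed,
            package_version = as.character(utils::packageVersion("morphodecode")))
  for (name in names(result$runs)) {
    r <- result$runs[[name]]
    write_tsv_meta(accuracy_timecourse(r$result),
                   file.path(out_dir, paste0("accuracy_", name, ".tsv")),
                   meta)
    write_segmentation_lexicon(r$lexicon,
                               file.path(out_dir,
                                         paste0("lexicon_", name, ".tsv")))
    write_vectors(r$store,
                  file.path(out_dir, paste0("segments_", name, ".vec")))
  }
  morph <- result$runs[[1]]
  write_newick(cluster_words(morph$word_vectors),
               file.path(out_dir, "dendrogram.nwk"))
  summary <- list(
    config_hash = hash,
    seed = cfg$synthetic$seed,
    n_perm = cfg$n_perm,
    level = cfg$level,
    test_window_center_s = result$test_window_center,
    comparison = result$comparison)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
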