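test_that("cosine distance matches closed forms and its invariances", {
  u <- c(1, 1); v <- c(1, 0)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(u, v), 1 - 1 / sqrt(2))
  expect_equal(cosine_distance(u, v), cosine_distance(v, u))
  expect_equal(cosine_distance(3.7 * u, v), cosine_distance(u, 0.2 * v))
  expect_equal(cosine_distance(c(1, 2), c(2, 4)), 0)
  expect_error(cosine_distance(c(0, 0), v), "zero")
  expect_error(cosine_distance(c(1, 2, 3), v), "mismatch")
})

test_that("word vectors are sums of segment vectors with multiplicity", {
  store <- segment_vector_store(
    matrix(c(1, 0, 0, 2), 2, byrow = TRUE, dimnames = list(c("a", "b"), NULL)))
  lex <- morphodecode:::new_segmented_lexicon(
    list(ab = c("a", "b"), aba = c("a", "b", "a"), solo = "a",
         gap = c("a", "zz"), lost = "zz"),
    segmentation_scheme("whole"))
  wv <- suppressWarnings(
    compose_word_vectors(lex, store, c("ab", "aba", "solo", "gap", "lost")))
  expect_equal(unname(wv["ab", ]), c(1, 2))
  expect_equal(unname(wv["aba", ]), c(2, 2))        # multiplicity counts
  expect_equal(unname(wv["solo", ]), c(1, 0))       # single segment unchanged
  expect_equal(unname(wv["gap", ]), c(1, 0))        # missing segment skipped
  cov <- attr(wv, "coverage")
  expect_identical(cov$missing$gap, "zz")
  expect_identical(cov$uncovered, "lost")           # flagged, not zeroed
  expect_true(all(is.na(wv["lost", ])))
  expect_error(compose_word_vectors(lex, store, "nothere"), "absent")
})

test_that("composition is linear in the store and matches whole-word lookup", {
  set.seed(3)
  labels <- c("ta", "lo", "jen")
  V1 <- matrix(rnorm(9), 3, dimnames = list(labels, NULL))
  V2 <- matrix(rnorm(9), 3, dimnames = list(labels, NULL))
  lex <- morphodecode:::new_segmented_lexicon(
    list(talojen = c("ta", "lo", "jen"), talo = c("ta", "lo")),
    segmentation_scheme("whole"))
  w <- c("talojen", "talo")
  c1 <- compose_word_vectors(lex, segment_vector_store(V1), w)
  c2 <- compose_word_vectors(lex, segment_vector_store(V2), w)
  c12 <- compose_word_vectors(lex, segment_vector_store(V1 + V2), w)
  expect_equal(unclass(c1) + unclass(c2), unclass(c12),
               ignore_attr = TRUE)

  whole <- build_segmented_lexicon("talojen", segmentation_scheme("whole"))
  store_w <- segment_vector_store(
    matrix(rnorm(4), 1, dimnames = list("talojen", NULL)))
  expect_equal(unname(compose_word_vectors(whole, store_w, "talojen")[1, ]),
               unname(store_w$vectors["talojen", ]))
})

test_that("skip-gram places segments with shared contexts closer", {
  # "aa" and "bb" occur in identical contexts; "cc" in disjoint contexts
  sentences <- c(replicate(60, paste("p", sample(c("aa", "bb"), 1), "q")),
                 replicate(30, "r cc s"))
  cfg <- embedding_config(dim = 16, window = 2, min_count = 5, epochs = 20,
                          seed = 11)
  store <- train_segment_vectors(sentences, cfg)
  expect_setequal(rownames(store$vectors), c("p", "q", "aa", "bb", "cc", "r", "s"))
  d_shared <- cosine_distance(store$vectors["aa", ], store$vectors["bb", ])
  d_control <- cosine_distance(store$vectors["aa", ], store$vectors["cc", ])
  expect_lt(d_shared, d_control)
  # determinism: same seed, same vectors
  store2 <- train_segment_vectors(sentences, cfg)
  expect_identical(store$vectors, store2$vectors)
})

test_that("min_count excludes rare segments; exclusion can empty the corpus", {
  sentences <- c(rep("aa bb", 10), rep("aa cc", 4))
  cfg <- embedding_config(dim = 4, window = 1, min_count = 5, epochs = 1,
                          seed = 1)
  store <- train_segment_vectors(sentences, cfg)
  expect_false("cc" %in% rownames(store$vectors))   # 4 < min_count
  expect_true(all(c("aa", "bb") %in% rownames(store$vectors)))

  cfg_x <- embedding_config(dim = 4, window = 1, min_count = 1, epochs = 1,
                            exclude_sentences_containing = c("aa"), seed = 1)
  expect_error(train_segment_vectors(sentences, cfg_x), "empty")
})

test_that("training respects the sentence-exclusion (OOV) contract", {
  sentences <- c(rep("x target y", 8), rep("x other y", 8))
  cfg <- embedding_config(dim = 4, window = 1, min_count = 2, epochs = 1,
                          exclude_sentences_containing = "target", seed = 1)
  store <- train_segment_vectors(sentences, cfg)
  expect_false("target" %in% rownames(store$vectors))
  expect_true("other" %in% rownames(store$vectors))
})

test_that("word2vec text format round-trips and validates its header", {
  set.seed(9)
  store <- segment_vector_store(
    matrix(rnorm(12), 4, dimnames = list(c("a", "b", "c", "ä"), NULL)))
  path <- withr::local_tempfile(fileext = ".vec")
  write_vectors(store, path)
  header <- strsplit(readLines(path, n = 1), " ")[[1]]
  expect_identical(header, c("4", "3"))
  back <- read_vectors(path)
  expect_identical(back$vectors, store$vectors)

  bad <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 2", "a 1 2", "b 3 4"), bad)
  expect_error(read_vectors(bad), "declares 3")
  writeLines(c("2 2", "a 1 2", "b 3 4 5"), bad)
  expect_error(read_vectors(bad), "dimension")
})

test_that("complete-linkage cosine clustering behaves and exports Newick", {
  X <- rbind(a = c(1, 0.01), b = c(1, 0.012), c = c(-1, 5))
  hc <- cluster_words(X)
  expect_equal(hc$merge[1, ], c(-1, -2))   # near-identical rows merge first
  expect_lt(hc$height[1], 1e-4)
  expect_false(is.unsorted(hc$height))     # complete linkage is monotone
  Xz <- rbind(a = c(1, 1), b = c(0, 0))
  expect_error(cluster_words(Xz), "zero")

  set.seed(5)
  Y <- matrix(rnorm(14), 7)
  rownames(Y) <- paste0("w", 1:7)
  hc2 <- cluster_words(Y)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc2, path)
  tree <- ape::read.tree(path)
  # cross-parser check: leaf-to-leaf path lengths in the parsed tree equal
  # twice the cophenetic merge heights of the clustering
  coph_tree <- ape::cophenetic.phylo(tree)
  coph_hc <- as.matrix(stats::cophenetic(hc2))
  expect_equal(coph_tree[rownames(coph_hc), colnames(coph_hc)],
               2 * coph_hc, tolerance = 1e-6, ignore_attr = TRUE)
})
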