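test_that("whole-word segmentation returns the word itself", {
  expect_identical(segment_whole("talojen"), "talojen")
  expect_identical(segment_whole("a"), "a")
  expect_identical(segment_whole("untalkable"), "untalkable")
  expect_error(segment_whole(""), "non-empty")
})

test_that("n-gram segmentation chunks left to right, short final chunk", {
  expect_identical(segment_ngram("untalkable", 3),
                   c("unt", "alk", "abl", "e"))
  expect_identical(segment_ngram("abc", 1), c("a", "b", "c"))
  segs <- segment_ngram("abcdefghi", 2)
  expect_length(segs, 5)
  expect_identical(nchar(segs[5]), 1L)
  expect_error(segment_ngram("abc", 0), "positive")
})

test_that("n-gram lengths count Unicode code points", {
  expect_identical(segment_ngram("äölkö", 2), c("äö", "lk", "ö"))
})

test_that("n-gram with k >= word length equals whole-word segmentation", {
  for (w in c("abc", "talojen", "ä")) {
    expect_identical(segment_ngram(w, nchar(w)), segment_whole(w))
    expect_identical(segment_ngram(w, nchar(w) + 3), segment_whole(w))
  }
})

test_that("random segmentation draws n from U{2..floor(l/2)} and conserves", {
  set.seed(1)
  for (rep in 1:50) {
    segs <- segment_random("kuusia")            # length 6: n in {2, 3}
    expect_true(length(segs) %in% 2:3)
    expect_identical(paste(segs, collapse = ""), "kuusia")
  }
  counts <- table(replicate(300, length(segment_random("kuusia"))))
  expect_setequal(names(counts), c("2", "3"))   # both values occur
  # l <= 3: empty draw set, word left whole; l in 4:5 forces n = 2
  expect_identical(segment_random("abc"), "abc")
  expect_length(segment_random("abcd"), 2)
  expect_length(segment_random("abcde"), 2)
})

test_that("segmentation schemes are deterministic per seed and conserve words", {
  words <- c("talojen", "kuusia", "abcdefghij", "äälykäs")
  for (scheme in list(segmentation_scheme("whole"),
                      segmentation_scheme("ngram", k = 2),
                      segmentation_scheme("ngram", k = 3),
                      segmentation_scheme("random", seed = 5))) {
    lex1 <- build_segmented_lexicon(words, scheme)
    lex2 <- build_segmented_lexicon(words, scheme)
    expect_identical(lex1$entries, lex2$entries)
    for (w in words) {
      expect_identical(paste(lex1$entries[[w]], collapse = ""), w)
      expect_gte(length(lex1$entries[[w]]), 1)
    }
  }
})

test_that("lexicon TSV round-trips, rejects duplicates and malformed lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "talojen\ttalo j en", "kuusia\tkuusi a"), path)
  lex <- read_segmentation_lexicon(path)
  expect_identical(lex$entries$talojen, c("talo", "j", "en"))
  expect_identical(lex$entries$kuusia, c("kuusi", "a"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation_lexicon(lex, out)
  expect_identical(read_segmentation_lexicon(out)$entries, lex$entries)

  writeLines(c("talojen\ttalo j en", "talojen\ttalojen"), path)
  expect_error(read_segmentation_lexicon(path, check_concatenation = FALSE),
               "duplicate.*line 2")
  writeLines("talojen\t  ", path)
  expect_error(read_segmentation_lexicon(path), "empty segments")
  writeLines("justaword", path)
  expect_error(read_segmentation_lexicon(path), "malformed.*line 1")
  # concatenation check is skippable for lemma-level morphs
  writeLines("talojen\ttalo jen_X", path)
  expect_error(read_segmentation_lexicon(path), "concatenate")
  expect_silent(read_segmentation_lexicon(path, check_concatenation = FALSE))
})

test_that("token streams are segmented in place, OOV passes through whole", {
  lex <- read_segmentation_lexicon(
    withr::local_tempfile(lines = "talojen\ttalo j en", fileext = ".tsv"))
  expect_message(
    out <- segment_tokens(c("iso", "talojen"), lex),
    "out-of-lexicon")
  expect_identical(out, c("iso", "talo", "j", "en"))
  expect_identical(segment_tokens(character(0), lex), character(0))
  lex2 <- build_segmented_lexicon("abcd", segmentation_scheme("ngram", k = 2))
  expect_identical(segment_tokens("abcd", lex2), c("ab", "cd"))
})

test_that("segmentation comparison assigns the five categories", {
  mk <- function(entries) morphodecode:::new_segmented_lexicon(
    entries, segmentation_scheme("whole"))
  ling <- mk(list(talojen = c("talo", "j", "en"),
                  kuusia = c("kuusi", "a"),
                  peruna = c("peru", "na"),
                  omena = c("ome", "na"),
                  kissan = c("kissa", "n")))
  stat <- mk(list(talojen = c("talo", "jen"),      # coarsening -> incomplete
                  kuusia = c("kuusi", "a"),        # identical
                  peruna = "peruna",               # unsegmented
                  omena = c("om", "ena"),          # bad boundary in stem
                  kissan = c("kissa", "n")))       # identical
  cmp <- compare_segmentations(stat, ling)
  expect_identical(unname(cmp$categories[c("talojen", "kuusia", "peruna",
                                           "omena", "kissan")]),
                   c("incomplete", "identical", "unsegmented",
                     "incorrect_stem", "identical"))
  expect_identical(sum(cmp$counts), 5L)

  # offending boundary after the first linguistic segment -> suffix error
  stat2 <- mk(list(talojen = c("talo", "je", "n"), kuusia = c("kuusi", "a"),
                   peruna = c("peru", "na"), omena = c("ome", "na"),
                   kissan = c("kissa", "n")))
  cmp2 <- compare_segmentations(stat2, ling)
  expect_identical(unname(cmp2$categories[["talojen"]]), "incorrect_suffix")
  expect_identical(unname(cmp2$categories[["omena"]]), "identical")

  expect_error(compare_segmentations(mk(list(a = "a")), ling),
               "symmetric difference")
})

test_that("comparison categories are exclusive, exhaustive and match a boundary-set oracle", {
  set.seed(42)
  words <- replicate(30, paste(sample(letters[1:6], sample(6:12, 1),
                                      replace = TRUE), collapse = ""))
  words <- unique(words)
  ling <- build_segmented_lexicon(words, segmentation_scheme("random", seed = 1))
  stat <- build_segmented_lexicon(words, segmentation_scheme("random", seed = 2))
  cmp <- compare_segmentations(stat, ling)
  expect_identical(sum(cmp$counts), length(words))
  boundaries <- function(segs) cumsum(nchar(segs))[-length(segs)]
  for (w in words) {
    bs <- boundaries(stat$entries[[w]])
    bl <- boundaries(ling$entries[[w]])
    cat_w <- cmp$categories[[w]]
    if (cat_w == "identical") expect_identical(sort(bs), sort(bl))
    if (cat_w == "incomplete") {
      expect_true(all(bs %in% bl))
      expect_false(setequal(bs, bl))
    }
    if (startsWith(cat_w, "incorrect")) expect_false(all(bs %in% bl))
    if (cat_w == "unsegmented") expect_length(stat$entries[[w]], 1)
  }
})
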