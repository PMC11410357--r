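#' Segmentation scheme descriptor
#'
#' Describes one way of cutting written words into subword segments. Four
#' schemes are supported: `"whole"` (no segmentation), `"ngram"` (contiguous
#' chunks of `k` characters), `"random"` (each word split at random interior
#' positions, reproducibly per `seed`), and `"lexicon"` (segments looked up
#' in an external word-to-segments table, e.g. linguistic morphemes or
#' Morfessor morphs).
#'
#' @param name One of `"whole"`, `"ngram"`, `"random"`, `"lexicon"`.
#' @param k Chunk length for the n-gram scheme (required iff `name="ngram"`).
#' @param seed Integer seed for the random scheme (required iff
#'   `name="random"`); fixes the segmentation of every word so that repeated
#'   builds are identical.
#' @param source_path Path to a segmentation lexicon TSV (required iff
#'   `name="lexicon"`).
#' @return An object of class `segmentation_scheme`.
#' @export
segmentation_scheme <- function(name = c("whole", "ngram", "random", "lexicon"),
                                k = NULL, seed = NULL, source_path = NULL) {
  name <- match.arg(name)
  if (name == "ngram") {
    if (is.null(k) || length(k) != 1L || !is.finite(k) || k < 1)
      stop("ngram scheme requires k >= 1", call. = FALSE)
    k <- as.integer(k)
  } else if (!is.null(k)) {
    stop("k is only meaningful for the ngram scheme", call. = FALSE)
  }
  if (name == "random") {
    if (is.null(seed)) stop("random scheme requires a seed", call. = FALSE)
    seed <- as.integer(seed)
  }
  if (name == "lexicon" && is.null(source_path))
    stop("lexicon scheme requires source_path", call. = FALSE)
  structure(list(name = name, k = k, seed = seed, source_path = source_path),
            class = "segmentation_scheme")
}

#' @export
print.segmentation_scheme <- function(x, ...) {
  extra <- switch(x$name,
    ngram = paste0(" (k=", x$k, ")"),
    random = paste0(" (seed=", x$seed, ")"),
    lexicon = paste0(" (", x$source_path, ")"),
    "")
  cat("<segmentation_scheme: ", x$name, extra, ">\n", sep = "")
  invisible(x)
}

#' Whole-word "segmentation"
#'
#' The degenerate scheme: the word is its own single segment.
#'
#' @param word Non-empty character string.
#' @return A character vector of length 1.
#' @export
segment_whole <- function(word) {
  if (!is.character(word) || length(word) != 1L || is.na(word) || !nzchar(word))
    stop("word must be a non-empty string", call. = FALSE)
  word
}

#' Character n-gram segmentation
#'
#' Splits a word into contiguous, non-overlapping, left-to-right chunks of
#' `k` characters; the final chunk may be shorter. Lengths are counted in
#' Unicode code points, so multibyte letters count as one character.
#'
#' @param word Non-empty character string.
#' @param k Chunk length, a positive integer.
#' @return Character vector of segments whose concatenation is `word`.
#' @export
segment_ngram <- function(word, k) {
  if (!is.character(word) || length(word) != 1L || is.na(word) || !nzchar(word))
    stop("word must be a non-empty string", call. = FALSE)
  if (length(k) != 1L || !is.finite(k) || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  l <- nchar(word, type = "chars")
  starts <- seq.int(1L, l, by = k)
  substring(word, starts, pmin(starts + k - 1L, l))
}

#' Random segmentation
#'
#' Splits a word into `n` segments at interior positions drawn uniformly
#' without replacement, where `n` is drawn from the discrete uniform over
#' `{2, ..., floor(l/2)}` and `l` is the word length in code points. Words of
#' length 3 or less are left whole (the draw set is empty); lengths 4-5
#' force `n = 2`. Uses the current RNG state: wrap calls (or use
#' [build_segmented_lexicon()]) with a seed for reproducibility.
#'
#' @param word Non-empty character string.
#' @return Character vector of segments whose concatenation is `word`.
#' @export
segment_random <- function(word) {
  if (!is.character(word) || length(word) != 1L || is.na(word) || !nzchar(word))
    stop("word must be a non-empty string", call. = FALSE)
  l <- nchar(word, type = "chars")
  nmax <- l %/% 2L
  if (nmax < 2L) return(word)
  n <- if (nmax == 2L) 2L else sample(2:nmax, 1L)
  cuts <- sort(sample.int(l - 1L, n - 1L))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, l)
  substring(word, starts, ends)
}

#' Build a segmented lexicon for a word list under a scheme
#'
#' Applies a [segmentation_scheme()] to each word, caching per word type so
#' that the random scheme assigns one fixed segmentation per word. For the
#' `"lexicon"` scheme the table is read from `scheme$source_path`.
#'
#' @param words Character vector of unique words.
#' @param scheme A [segmentation_scheme()].
#' @return A `segmented_lexicon`: list with `entries` (named list mapping
#'   word to its character vector of segments, in input order) and `scheme`.
#' @export
build_segmented_lexicon <- function(words, scheme) {
  stopifnot(inherits(scheme, "segmentation_scheme"))
  if (anyDuplicated(words)) stop("word list contains duplicates", call. = FALSE)
  if (scheme$name == "lexicon") {
    lex <- read_segmentation_lexicon(scheme$source_path)
    missing <- setdiff(words, names(lex$entries))
    if (length(missing))
      stop("words absent from lexicon file: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    entries <- lex$entries[words]
  } else {
    entries <- with_seed(scheme$seed, {
      lapply(words, function(w) switch(scheme$name,
        whole = segment_whole(w),
        ngram = segment_ngram(w, scheme$k),
        random = segment_random(w)))
    })
    names(entries) <- words
  }
  new_segmented_lexicon(entries, scheme)
}

new_segmented_lexicon <- function(entries, scheme) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  if (anyDuplicated(names(entries)))
    stop("duplicate words in lexicon", call. = FALSE)
  if (any(vapply(entries, length, 1L) < 1L))
    stop("every word needs at least one segment", call. = FALSE)
  structure(list(entries = entries, scheme = scheme),
            class = "segmented_lexicon")
}

#' @export
print.segmented_lexicon <- function(x, ...) {
  cat("<segmented_lexicon: ", length(x$entries), " words, scheme ",
      if (inherits(x$scheme, "segmentation_scheme")) x$scheme$name else "?",
      ">\n", sep = "")
  invisible(x)
}

#' Segments of one word from a lexicon
#' @param lexicon A `segmented_lexicon`.
#' @param word Word to look up.
#' @return Character vector of segments.
#' @export
lexicon_segments <- function(lexicon, word) {
  segs <- lexicon$entries[[word]]
  if (is.null(segs)) stop("word not in lexicon: ", word, call. = FALSE)
  segs
}

#' Read a segmentation lexicon from TSV
#'
#' Format: one entry per line, `word<TAB>seg1 seg2 ...`, UTF-8, lines
#' starting with `#` ignored. By default the concatenation of each word's
#' segments must reproduce the word exactly; set `check_concatenation =
#' FALSE` for lexicons with normalized (lemma-level) morphs where surface
#' alternations break this.
#'
#' @param path File path.
#' @param check_concatenation Verify the concatenation invariant.
#' @return A `segmented_lexicon` with scheme `"lexicon"`.
#' @export
read_segmentation_lexicon <- function(path, check_concatenation = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  entries <- list()
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]))
      stop(sprintf("malformed lexicon line %d: %s", i, lines[i]),
           call. = FALSE)
    segs <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(segs) == 0L || any(!nzchar(segs)))
      stop(sprintf("empty segments field on line %d", i), call. = FALSE)
    if (!is.null(entries[[parts[1]]]))
      stop(sprintf("duplicate word '%s' on line %d", parts[1], i),
           call. = FALSE)
    if (check_concatenation && paste(segs, collapse = "") != parts[1])
      stop(sprintf("segments do not concatenate to word on line %d", i),
           call. = FALSE)
    entries[[parts[1]]] <- segs
  }
  new_segmented_lexicon(
    entries,
    structure(list(name = "lexicon", source_path = path),
              class = "segmentation_scheme"))
}

#' Write a segmentation lexicon as TSV
#' @param lexicon A `segmented_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_lexicon <- function(lexicon, path) {
  lines <- vapply(names(lexicon$entries), function(w) {
    paste0(w, "\t", paste(lexicon$entries[[w]], collapse = " "))
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Segment a token stream
#'
#' Replaces each word token by its ordered segments. Tokens missing from a
#' lexicon pass through whole; the number of such out-of-lexicon tokens is
#' reported via a message.
#'
#' @param tokens Character vector of word tokens.
#' @param lexicon A `segmented_lexicon`.
#' @param quiet Suppress the out-of-lexicon message.
#' @return Character vector of segment tokens.
#' @export
segment_tokens <- function(tokens, lexicon, quiet = FALSE) {
  if (length(tokens) == 0L) return(character(0))
  hit <- tokens %in% names(lexicon$entries)
  if (!quiet && any(!hit))
    message(sum(!hit), " out-of-lexicon token(s) passed through whole")
  out <- vector("list", length(tokens))
  out[hit] <- lexicon$entries[tokens[hit]]
  out[!hit] <- as.list(tokens[!hit])
  unlist(out, use.names = FALSE)
}

# Interior boundary positions (in code points from word start) implied by a
# segment list; a boundary b means "cut after character b".
segment_boundaries <- function(segments) {
  cs <- cumsum(nchar(segments, type = "chars"))
  cs[-length(cs)]
}

#' Compare a statistical segmentation against a linguistic reference
#'
#' Labels every word with exactly one category: `identical` (equal segment
#' lists), `unsegmented` (statistical left the word whole where the
#' reference splits it), `incomplete` (statistical splits, every statistical
#' boundary is also a reference boundary, but some reference boundaries are
#' missed), `incorrect_stem` / `incorrect_suffix` (at least one statistical
#' boundary is not a reference boundary; classified `stem` when the first
#' offending boundary lies at or before the end of the first reference
#' segment, `suffix` otherwise).
#'
#' @param statistical,linguistic Two `segmented_lexicon`s over identical
#'   word sets.
#' @return List with `categories` (named character vector, one per word) and
#'   `counts` (named integer vector over the five categories; sums to the
#'   word count).
#' @export
compare_segmentations <- function(statistical, linguistic) {
  ws <- names(statistical$entries)
  wl <- names(linguistic$entries)
  if (!setequal(ws, wl)) {
    diff <- union(setdiff(ws, wl), setdiff(wl, ws))
    stop("word sets differ; symmetric difference: ",
         paste(utils::head(diff, 10), collapse = ", "), call. = FALSE)
  }
  cats <- vapply(ws, function(w) {
    s <- statistical$entries[[w]]
    l <- linguistic$entries[[w]]
    if (identical(s, l)) return("identical")
    if (length(s) == 1L && length(l) > 1L) return("unsegmented")
    bs <- segment_boundaries(s)
    bl <- segment_boundaries(l)
    offending <- setdiff(bs, bl)
    if (length(offending) == 0L) return("incomplete")
    if (min(offending) <= nchar(l[1], type = "chars")) "incorrect_stem"
    else "incorrect_suffix"
  }, "")
  levels <- c("identical", "unsegmented", "incomplete",
              "incorrect_stem", "incorrect_suffix")
  counts <- vapply(levels, function(cl) sum(cats == cl), 1L)
  list(categories = cats, counts = counts)
}
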