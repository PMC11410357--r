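#' Configuration for segment-vector training
#'
#' Contract for the skip-gram segment embeddings: vector dimension, symmetric
#' context window (segments considered on each side of the target), and the
#' minimum corpus frequency a segment needs for a vector to be trained.
#' Defaults mirror the full-scale setting (300 dimensions, window 7,
#' min_count 50); toy corpora use smaller values. Negative-sampling count and
#' epoch number are unconstrained by the decoding contract and exposed here.
#'
#' @param dim Vector dimension D.
#' @param window Context window N (N segments before and after).
#' @param min_count Minimum segment frequency; rarer segments get no vector.
#' @param negative Negative samples per positive pair.
#' @param epochs Training epochs.
#' @param learning_rate Initial SGD learning rate (linear decay).
#' @param exclude_sentences_containing Optional character vector of surface
#'   words; any sentence containing one of them (as a whitespace token) is
#'   dropped before segmentation. This is the out-of-vocabulary regime:
#'   target words never appear in training, so their vectors must be composed
#'   from segments learned elsewhere.
#' @param seed Integer seed for deterministic training.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(dim = 300, window = 7, min_count = 50,
                             negative = 5, epochs = 5, learning_rate = 0.025,
                             exclude_sentences_containing = NULL, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, min_count >= 1, negative >= 0, epochs >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 exclude_sentences_containing = exclude_sentences_containing,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Segment vector store
#'
#' Wraps a labels-by-dimension numeric matrix mapping segment labels to
#' embedding vectors.
#'
#' @param vectors Numeric matrix with one row per segment label (rownames
#'   required, unique) and `D` columns; all entries finite.
#' @return A `segment_vector_store`.
#' @export
segment_vector_store <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)))
    stop("vectors need unique rownames (segment labels)", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("non-finite entries in vector store", call. = FALSE)
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "segment_vector_store")
}

#' @export
print.segment_vector_store <- function(x, ...) {
  cat("<segment_vector_store: ", nrow(x$vectors), " segments, dim ",
      x$dim, ">\n", sep = "")
  invisible(x)
}

#' Train segment vectors with skip-gram negative sampling
#'
#' Tokenizes the corpus (whitespace), optionally drops sentences containing
#' excluded surface words, replaces each token by its segments under
#' `lexicon`, and trains a skip-gram model with negative sampling over the
#' segment stream. Only segments with corpus frequency at least
#' `config$min_count` receive vectors. The trainer is a minimal,
#' deterministic single-threaded implementation (compiled inner loop); it
#' satisfies the defining distributional property that segments sharing
#' contexts obtain nearby vectors.
#'
#' @param sentences Character vector, one sentence per element.
#' @param config An [embedding_config()].
#' @param lexicon Optional `segmented_lexicon`; if `NULL`, tokens are used
#'   unsegmented (whole-word training).
#' @return A `segment_vector_store`.
#' @export
train_segment_vectors <- function(sentences, config, lexicon = NULL) {
  stopifnot(inherits(config, "embedding_config"))
  if (length(sentences) == 0L) stop("empty corpus", call. = FALSE)
  toks <- strsplit(sentences, "\\s+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  excl <- config$exclude_sentences_containing
  if (!is.null(excl)) {
    keep <- !vapply(toks, function(x) any(x %in% excl), TRUE)
    toks <- toks[keep]
  }
  toks <- toks[lengths(toks) > 0L]
  if (length(toks) == 0L)
    stop("corpus empty after sentence exclusion", call. = FALSE)
  if (!is.null(lexicon))
    toks <- lapply(toks, segment_tokens, lexicon = lexicon, quiet = TRUE)

  counts <- table(unlist(toks, use.names = FALSE))
  vocab <- names(counts)[counts >= config$min_count]
  if (length(vocab) == 0L)
    stop("no segment reaches min_count", call. = FALSE)
  idx <- lapply(toks, function(x) {
    m <- match(x, vocab)
    m[!is.na(m)] - 1L   # 0-based; under-frequency segments dropped in place
  })
  idx <- idx[lengths(idx) > 0L]
  mat <- .sgns_train(idx, as.integer(counts[vocab]), config$dim,
                     config$window, config$negative, config$epochs,
                     config$learning_rate, config$seed)
  rownames(mat) <- vocab
  segment_vector_store(mat)
}

#' Compose word vectors by summing segment vectors
#'
#' The word vector of `w` is the sum, with multiplicity, of the store vectors
#' of `w`'s segments. Segments absent from the store are skipped and recorded
#' in the coverage report; words with no covered segment at all get `NA` rows
#' and are listed in `coverage$uncovered` for caller-side exclusion (they
#' cannot be represented and must be omitted from decoder training).
#'
#' @param lexicon A `segmented_lexicon` covering all `words`.
#' @param store A `segment_vector_store`.
#' @param words Character vector of words to compose.
#' @return A numeric matrix (words x D, rownames = `words`) of class
#'   `word_vector_matrix`, with attribute `coverage`: list with per-word
#'   `found`/`missing` segment lists and the `uncovered` word vector.
#' @export
compose_word_vectors <- function(lexicon, store, words) {
  absent <- setdiff(words, names(lexicon$entries))
  if (length(absent))
    stop("words absent from lexicon: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  D <- store$dim
  labels <- rownames(store$vectors)
  mat <- matrix(NA_real_, nrow = length(words), ncol = D,
                dimnames = list(words, colnames(store$vectors)))
  found <- missing <- vector("list", length(words))
  names(found) <- names(missing) <- words
  for (i in seq_along(words)) {
    segs <- lexicon$entries[[words[i]]]
    hit <- segs %in% labels
    found[[i]] <- segs[hit]
    missing[[i]] <- segs[!hit]
    if (any(hit)) {
      mat[i, ] <- colSums(store$vectors[segs[hit], , drop = FALSE])
    }
  }
  uncovered <- words[lengths(found) == 0L]
  if (length(uncovered))
    warning(length(uncovered), " word(s) with no covered segment; ",
            "rows set to NA (see attr(., 'coverage')$uncovered)",
            call. = FALSE)
  structure(mat,
            coverage = list(found = found, missing = missing,
                            uncovered = uncovered),
            class = c("word_vector_matrix", "matrix", "array"))
}

#' Cosine distance between two vectors
#'
#' `1 - u.v / (|u| |v|)`, in `[0, 2]`. Undefined (error) for zero vectors.
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return Scalar distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for zero vectors", call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

# All pairwise cosine distances between the rows of a matrix.
cosine_distance_matrix <- function(X) {
  n <- sqrt(rowSums(X^2))
  if (any(n == 0)) stop("zero row in matrix", call. = FALSE)
  d <- 1 - tcrossprod(X / n)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Complete-linkage clustering of word vectors under cosine distance
#'
#' Agglomerative clustering where the distance between clusters is the
#' largest cosine distance between any two members. Used to visualize how a
#' composed word-vector space organizes (semantic clusters vs shared-suffix
#' clusters).
#'
#' @param wvm Word-vector matrix (rows = words, no `NA`/zero rows; at least
#'   two words).
#' @return An [stats::hclust] object with word labels.
#' @export
cluster_words <- function(wvm) {
  X <- unclass(wvm)
  attr(X, "coverage") <- NULL
  if (nrow(X) < 2) stop("need at least 2 words", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite rows in matrix", call. = FALSE)
  hclust(as.dist(cosine_distance_matrix(X)), method = "complete")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height 0).
#' Labels are sanitized: parentheses, commas, colons, semicolons and
#' whitespace are replaced by `_`.
#'
#' @param hc An [stats::hclust] object.
#' @return A single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(hc) {
  labels <- gsub("[(),:;\\s]+", "_", hc$labels, perl = TRUE)
  rec <- function(node, parent_height) {
    if (node < 0) {
      paste0(labels[-node], ":", format(parent_height, digits = 10))
    } else {
      h <- hc$height[node]
      kids <- hc$merge[node, ]
      paste0("(", rec(kids[1], h), ",", rec(kids[2], h), "):",
             format(parent_height - h, digits = 10))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  kids <- hc$merge[root, ]
  paste0("(", rec(kids[1], h), ",", rec(kids[2], h), ");")
}

#' Write a vector store in word2vec text format
#'
#' Header line `count dim`, then one `label v1 ... vD` line per segment.
#'
#' @param store A `segment_vector_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(store, path) {
  V <- store$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(V), ncol(V)), con)
  body <- vapply(seq_len(nrow(V)), function(i) {
    paste(rownames(V)[i], paste(sprintf("%.17g", V[i, ]), collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a vector store in word2vec text format
#'
#' @param path Input path.
#' @return A `segment_vector_store`.
#' @export
read_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty vector file", call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed header line", call. = FALSE)
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != hdr[1])
    stop(sprintf("header declares %d vectors but file has %d lines",
                 hdr[1], length(body)), call. = FALSE)
  parts <- strsplit(trimws(body), "\\s+")
  labs <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  if (any(lengths(vals) != hdr[2]))
    stop("vector dimension does not match header", call. = FALSE)
  mat <- do.call(rbind, vals)
  rownames(mat) <- labs
  segment_vector_store(mat)
}
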