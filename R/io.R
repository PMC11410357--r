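# Small FNV-style hash of a serialized R object; used to stamp outputs with
# a config identifier so result files can be matched to the run that
# produced them.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((h * 16777619) + b) %% 4294967296
  sprintf("%08x", h)
}

# TSV writer with `#key=value` metadata comment lines; all files UTF-8.
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("#", names(meta), "=", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- if (length(meta_lines)) {
    kv <- sub("^#", "", meta_lines)
    pos <- regexpr("=", kv, fixed = TRUE)
    stats::setNames(substring(kv, pos + 1), substring(kv, 1, pos - 1))
  } else character(0)
  df <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write an epochs array as self-describing TSV
#'
#' Plain-text serialization: `#key=value` metadata comment lines (`sfreq`,
#' `tmin`, units), then one row per word-by-sensor combination with one
#' column per time sample. Round-trips exactly through
#' [read_epochs_tsv()] for data representable in 17 significant digits.
#'
#' @param epochs An `epochs_array`.
#' @param path Output path.
#' @param units Amplitude unit label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_epochs_tsv <- function(epochs, path, units = "arbitrary") {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  df <- data.frame(word = rep(epochs$words, each = d[2]),
                   sensor = rep(seq_len(d[2]), times = d[1]),
                   stringsAsFactors = FALSE)
  flat <- matrix(sprintf("%.17g", flat), nrow = nrow(flat))
  colnames(flat) <- paste0("t", seq_len(d[3]))
  write_tsv_meta(cbind(df, flat), path,
                 meta = c(sfreq = sprintf("%.17g", epochs$sfreq),
                          tmin = sprintf("%.17g", epochs$tmin),
                          units = units))
}

#' Read an epochs array written by [write_epochs_tsv()]
#' @param path Input path.
#' @return An `epochs_array`.
#' @export
read_epochs_tsv <- function(path) {
  df <- read_tsv_meta(path)
  meta <- attr(df, "meta")
  if (!all(c("sfreq", "tmin") %in% names(meta)))
    stop("epochs TSV missing sfreq/tmin metadata", call. = FALSE)
  words <- unique(df$word)
  sensors <- sort(unique(df$sensor))
  tcols <- grep("^t\\d+$", names(df), value = TRUE)
  data <- array(NA_real_, c(length(words), length(sensors), length(tcols)))
  vals <- as.matrix(df[, tcols])
  wi <- match(df$word, words)
  si <- match(df$sensor, sensors)
  for (r in seq_len(nrow(df))) data[wi[r], si[r], ] <- vals[r, ]
  if (any(is.na(data))) stop("incomplete epochs TSV", call. = FALSE)
  epochs_array(data, sfreq = as.numeric(meta[["sfreq"]]),
               tmin = as.numeric(meta[["tmin"]]), words = words)
}

#' Write a dendrogram to a Newick file
#' @param hc An [stats::hclust] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  writeLines(dendrogram_newick(hc), path)
  invisible(path)
}
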