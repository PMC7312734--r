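# File formats: FASTA sequences, TSV pair lists, TSV feature matrices
# (with a layout-version header), plus the dataset length filter.

.feature_layout_tag <- "#ppiwave-features layout=v1"

#' Read protein sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines and lowercase accepted; record
#' ids are the first whitespace-delimited token of the header. Duplicate
#' ids are an error; an empty file returns an empty vector with a
#' warning.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) {
    warning("no FASTA records in ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write a pair list as tab-separated text
#'
#' Columns `id_a`, `id_b`, `label` (1 = interacting, 0 = not); the writer
#' also emits an `origin` column (`fwd`/`bwd`) when present, for auditing
#' augmented sets.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "label")
  if (!all(need %in% names(df)))
    stop("pair file must have columns id_a, id_b, label: ", path)
  if (!all(df$label %in% c(0L, 1L)))
    stop("pair labels must be 0 or 1: ", path)
  df
}

#' @rdname read_pairs
#' @param pairs data frame with `id_a`, `id_b`, `label` (and optionally
#'   `origin`).
#' @export
write_pairs <- function(pairs, path) {
  keep <- intersect(c("id_a", "id_b", "label", "origin"), names(pairs))
  utils::write.table(pairs[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a protein feature matrix as delimited text
#'
#' One row per protein: id column plus the 600 descriptor columns in
#' [feature_layout()] order. The first line is a layout-version header;
#' the reader rejects files with a different layout version.
#'
#' @param features matrix from [featurize_proteins()].
#' @param path TSV file.
#' @return `read_feature_matrix` returns the matrix (rownames = ids).
#' @export
write_feature_matrix <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.feature_layout_tag, con)
  df <- data.frame(id = rownames(features), features, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(first, .feature_layout_tag))
    stop("unrecognized feature-matrix layout header in ", path,
         " (expected '", .feature_layout_tag, "')")
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  if (ncol(m) != 600L)
    stop("feature matrix must have 600 columns, found ", ncol(m))
  m
}

#' Filter sequences (and their pairs) by length
#'
#' Keeps sequences with `min_len <= L <= max_len` — the closed interval,
#' so length 64 and length 1200 are kept while 63 and 1201 are dropped.
#' Pairs referencing a dropped protein are dropped and reported.
#'
#' @param sequences named character vector.
#' @param min_len,max_len accepted length bounds.
#' @param pairs optional pair data frame to filter alongside.
#' @return list with `sequences` (kept), `dropped` (data frame id,
#'   length, reason) and, when `pairs` was given, `pairs` (kept) and
#'   `pairs_dropped`.
#' @export
filter_by_length <- function(sequences, min_len = 64L, max_len = 1200L,
                             pairs = NULL) {
  lens <- nchar(sequences)
  too_short <- lens < min_len
  too_long <- lens > max_len
  drop <- too_short | too_long
  dropped <- data.frame(
    id = names(sequences)[drop],
    length = unname(lens[drop]),
    reason = ifelse(too_short[drop], paste0("shorter than ", min_len),
                    paste0("longer than ", max_len)),
    stringsAsFactors = FALSE)
  out <- list(sequences = sequences[!drop], dropped = dropped)
  if (!is.null(pairs)) {
    bad <- pairs$id_a %in% dropped$id | pairs$id_b %in% dropped$id
    out$pairs <- pairs[!bad, , drop = FALSE]
    out$pairs_dropped <- pairs[bad, , drop = FALSE]
  }
  out
}
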