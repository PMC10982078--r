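# TSV/FASTA readers and writers. All TSVs are UTF-8, tab-delimited, with
# a header row, so outputs are bit-exact diffable.

#' Write / read a presence/absence matrix TSV
#'
#' First column `sample`, remaining columns transcript IDs, cells 0/1.
#'
#' @param m 0/1 matrix with sample rownames and transcript colnames.
#' @param path file path.
#' @return `read_presence_tsv` returns the integer matrix; the writer
#'   returns `path` invisibly.
#' @export
write_presence_tsv <- function(m, path) {
  check_presence_matrix(m)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample") stop("first column must be 'sample'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  check_presence_matrix(m)
  m
}

#' Write / read sequences as FASTA
#'
#' Thin wrappers around `Biostrings` keeping the package's plain
#' named-character-vector convention.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read an abundance table TSV
#'
#' Columns `sample`, `pct_virus`, `pct_wolbachia`.
#'
#' @param table the abundance data.frame.
#' @param path file path.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(all(c("sample", "pct_virus", "pct_wolbachia") %in% names(table)))
  write.table(table[, c("sample", "pct_virus", "pct_wolbachia")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "pct_virus", "pct_wolbachia")
  if (!all(need %in% names(df))) {
    stop("abundance TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write / read a distance matrix TSV
#'
#' Square layout: first column `seq_id`, remaining columns the sequence
#' IDs, cells fractional distances (full symmetric matrix).
#'
#' @param D a `pdist_matrix` or named symmetric matrix.
#' @param path file path.
#' @export
write_distance_tsv <- function(D, path) {
  d <- as_dist_matrix(D)
  df <- data.frame(seq_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a sequence-to-group assignment TSV
#'
#' Columns `seq_id`, `group`.
#'
#' @param path file path.
#' @return data.frame with `seq_id` and `group`.
#' @export
read_groups_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("seq_id", "group") %in% names(df))) {
    stop("groups TSV needs columns seq_id, group")
  }
  df
}

#' Read an anchors TSV
#'
#' Columns `virus_id`, `transcript_id`; one [anchor_set()] per virus.
#'
#' @param path file path.
#' @return named list of `anchor_set` objects, one per virus.
#' @export
read_anchors_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("virus_id", "transcript_id") %in% names(df))) {
    stop("anchors TSV needs columns virus_id, transcript_id")
  }
  sp <- split(df$transcript_id, df$virus_id)
  mapply(anchor_set, names(sp), sp, SIMPLIFY = FALSE)
}
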