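.frame_order <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate a nucleotide sequence
#'
#' Codon-by-codon translation using an NCBI genetic code table
#' (standard code by default). Stop codons are rendered `*`; any codon
#' containing a character outside `ACGT` (ambiguity codes, `N`) is
#' rendered `X`.
#'
#' @param nt nucleotide string, length divisible by 3 (case-insensitive).
#' @param genetic_code NCBI genetic code table ID (default `"1"`,
#'   standard). Only the standard code is exercised by the pipeline; the
#'   parameter exists for extension.
#' @return amino-acid string of length `nchar(nt) / 3`.
#' @examples
#' translate_nt("ATGTAA")  # "M*"
#' @export
translate_nt <- function(nt, genetic_code = "1") {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length must be divisible by 3")
  if (n == 0L) return("")
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Stop/start codon tests on a vector of codons; codons containing N (or
# any non-ACGT character) never match either.
.is_stop <- function(codons) codons %in% c("TAA", "TAG", "TGA")
.is_start <- function(codons) codons == "ATG"

# ORF runs in one frame of one strand. codons: character vector of whole
# codons in reading order. Returns list of (first_codon, n_codons)
# 0-based codon indices, nt lengths applied later.
.frame_runs <- function(codons, start_required) {
  stops <- which(.is_stop(codons))
  bounds <- c(0L, stops, length(codons) + 1L)  # virtual stops at both ends
  runs <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + 1L       # first codon index of the open run
    hi <- bounds[i + 1L] - 1L  # last codon index (excludes the stop)
    if (hi < lo) next
    if (start_required) {
      atg <- which(.is_start(codons[lo:hi]))
      if (!length(atg)) next
      lo <- lo + atg[1L] - 1L
    }
    runs[[length(runs) + 1L]] <- c(lo, hi)
  }
  runs
}

#' Find open reading frames in all six frames
#'
#' Scans a nucleotide sequence in the three forward and three reverse
#' frames for ORFs, with the two ORF semantics of EMBOSS `getorf`:
#'
#' * `stop_to_stop` (getorf `-find 2`/`-find 0`; the pipeline default):
#'   an ORF is a maximal stop-free codon run between stop codons, with
#'   the sequence ends acting as virtual stops.
#' * `start_to_stop` (getorf `-find 3`/`-find 1`): the run starts at the
#'   first `ATG` after the previous stop (only `ATG`, no alternative
#'   start codons) and extends to the next stop or sequence end.
#'
#' The `_nt`/`_aa` suffix of `mode` records whether downstream reporting
#' is nucleotide- or protein-oriented; the ORF set is identical and both
#' sequences are always returned. Reported `nt_seq` excludes the
#' terminating stop codon and `min_len` applies to that stop-free length.
#' Codons containing `N` never match a start or stop and translate to
#' `X`.
#'
#' Coordinates are 0-based half-open on the forward strand: for
#' reverse-strand ORFs `nt_seq` is the reverse complement of the slice
#' `[start, end)`. Frames are `1, 2, 3` for forward offsets 0-2 and
#' `-1, -2, -3` for the same offsets on the reverse complement.
#'
#' @param seq nucleotide string over `ACGTN` (case-insensitive).
#' @param mode one of `"stop_to_stop_nt"`, `"start_to_stop_nt"`,
#'   `"stop_to_stop_aa"`, `"start_to_stop_aa"`.
#' @param min_len minimum ORF length in nt (stop codon excluded).
#' @param genetic_code NCBI genetic code table ID (see [translate_nt()]).
#' @param seq_id label copied into the output.
#' @return data.frame with columns `seq_id`, `frame`, `start`, `end`,
#'   `length_nt`, `nt_seq`, `aa_seq`, sorted by `start` then frame
#'   (`+1, +2, +3, -1, -2, -3`).
#' @examples
#' find_orfs("ATGAAATAA", mode = "start_to_stop_nt", min_len = 3)
#' @export
find_orfs <- function(seq, mode = c("stop_to_stop_nt", "start_to_stop_nt",
                                    "stop_to_stop_aa", "start_to_stop_aa"),
                      min_len = 0L, genetic_code = "1", seq_id = "seq") {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 0)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  start_required <- startsWith(mode, "start_to_stop")
  L <- nchar(seq)
  strands <- list(`1` = seq, `-1` = reverse_complement(seq))

  out <- list()
  for (sgn in c(1L, -1L)) {
    s_seq <- strands[[as.character(sgn)]]
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      starts <- off + seq.int(1L, by = 3L, length.out = n_codons)
      codons <- substring(s_seq, starts, starts + 2L)
      for (run in .frame_runs(codons, start_required)) {
        lo <- run[1L]; hi <- run[2L]
        len_nt <- 3L * (hi - lo + 1L)
        if (len_nt < min_len) next
        # 0-based coords on the scanned strand
        s0 <- off + 3L * (lo - 1L)
        e0 <- s0 + len_nt
        nt <- substr(s_seq, s0 + 1L, e0)
        if (sgn == 1L) {
          fwd_start <- s0; fwd_end <- e0
        } else {
          fwd_start <- L - e0; fwd_end <- L - s0
        }
        out[[length(out) + 1L]] <- data.frame(
          seq_id = seq_id, frame = sgn * (off + 1L),
          start = fwd_start, end = fwd_end, length_nt = len_nt,
          nt_seq = nt, aa_seq = translate_nt(nt, genetic_code),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), frame = integer(), start = integer(),
               end = integer(), length_nt = integer(), nt_seq = character(),
               aa_seq = character(), stringsAsFactors = FALSE)
  res <- res[order(res$start, match(res$frame, .frame_order)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Maximum ORF length per sequence
#'
#' Convenience wrapper feeding the candidate-segment screen: runs
#' [find_orfs()] on each sequence and returns the longest ORF length in
#' nt (0 if a sequence has no ORF at `min_len`).
#'
#' @param seqs named character vector of nucleotide sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @inheritParams find_orfs
#' @return named numeric vector of maximum ORF lengths (nt).
#' @export
max_orf_lengths <- function(seqs, mode = "stop_to_stop_nt", min_len = 0L,
                            genetic_code = "1") {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  vapply(names(seqs), function(id) {
    orfs <- find_orfs(seqs[[id]], mode = mode, min_len = min_len,
                      genetic_code = genetic_code, seq_id = id)
    if (nrow(orfs)) max(orfs$length_nt) else 0
  }, numeric(1))
}
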