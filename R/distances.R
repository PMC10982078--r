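#' Discard duplicate sequences within each sample
#'
#' Before distance analysis, exact duplicate sequences recovered from the
#' same sample (e.g. redundant assembly isoforms of one viral transcript)
#' are reduced to their first occurrence. Identical sequences found in
#' *different* samples are retained — cross-sample identity is a
#' biological signal. Comparison is case-folded.
#'
#' @param records data.frame with columns `sample` and `sequence`
#'   (additional columns such as `seq_id` are carried through).
#' @return the filtered data.frame, original order preserved.
#' @examples
#' d <- data.frame(sample = c("a", "a", "b"),
#'                 sequence = c("ACGT", "acgt", "ACGT"))
#' dedupe_within_sample(d)
#' @export
dedupe_within_sample <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample", "sequence") %in% names(records)))
  key <- paste(records$sample, toupper(records$sequence), sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Site inclusion mask for one pair: both characters must be unambiguous
# bases. Gaps, N and any other IUPAC ambiguity code exclude the site.
.site_ok <- function(chars) chars %in% c("A", "C", "G", "T")

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the compared positions, with
#' pairwise deletion: a site is excluded for this pair when either
#' sequence has a gap (`-`) or an ambiguous base (`N` or any other
#' non-`ACGT` character). No multiple-substitution correction is applied.
#'
#' @param a,b aligned sequences of equal length (case-insensitive).
#' @return list with `distance` (fraction in `[0, 1]`) and `sites`
#'   (number of compared positions).
#' @examples
#' p_distance("A-CGT", "AACGA")  # 1 mismatch over 4 compared sites
#' @export
p_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- .site_ok(ca) & .site_ok(cb)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  list(distance = sum(ca[ok] != cb[ok]) / n, sites = n)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Computes all pairwise uncorrected p-distances of an aligned sequence
#' set. Under `pairwise_deletion` (the default, matching MEGA's usual
#' setting) sites are excluded per pair; under `complete_deletion` every
#' column containing a gap or ambiguity in *any* sequence is removed
#' once, before any pair is compared.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   over `ACGTN-` (case-insensitive), or a `Biostrings::DNAStringSet`.
#' @param policy `"pairwise_deletion"` or `"complete_deletion"`.
#' @return object of class `pdist_matrix`: list with `ids`, `d`
#'   (symmetric matrix of fractions, zero diagonal) and `sites`
#'   (per-pair compared-site counts).
#' @examples
#' fam <- simulate_divergent_family(
#'   clade_scenario(c(2, 2), 500, 0.01, 0.2), seed = 3)
#' distance_matrix(fam$sequences)
#' @export
distance_matrix <- function(aln,
                            policy = c("pairwise_deletion",
                                       "complete_deletion")) {
  policy <- match.arg(policy)
  if (methods::is(aln, "DNAStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (anyDuplicated(names(aln))) stop("sequence IDs must be unique")
  k <- length(aln)
  if (k < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  chars <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  if (policy == "complete_deletion") {
    keep <- apply(chars, 2L, function(col) all(.site_ok(col)))
    if (!any(keep)) stop("no comparable sites after complete deletion")
    chars <- chars[, keep, drop = FALSE]
  }
  ok <- matrix(.site_ok(chars), nrow = k)
  d <- matrix(0, k, k, dimnames = list(names(aln), names(aln)))
  sites <- matrix(ncol(chars), k, k, dimnames = dimnames(d))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      use <- ok[i, ] & ok[j, ]
      n <- sum(use)
      if (n == 0L) {
        stop(sprintf("no comparable sites for pair %s / %s",
                     names(aln)[i], names(aln)[j]))
      }
      d[i, j] <- d[j, i] <- sum(chars[i, use] != chars[j, use]) / n
      sites[i, j] <- sites[j, i] <- n
    }
  }
  structure(list(ids = names(aln), d = d, sites = sites),
            class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, percent = TRUE, ...) {
  cat(sprintf("p-distance matrix: %d sequences\n", length(x$ids)))
  m <- if (percent) round_half_up(100 * x$d, 1) else x$d
  print(m, ...)
  invisible(x)
}

# Accept a pdist_matrix or a plain symmetric numeric matrix of fractions.
as_dist_matrix <- function(D) {
  if (inherits(D, "pdist_matrix")) return(D$d)
  if (is.matrix(D) && !is.null(rownames(D))) return(D)
  stop("D must be a pdist_matrix or a named symmetric matrix")
}

#' Within- and between-group mean p-distances
#'
#' Summarises a pairwise distance matrix by group (clade): the within
#' mean of a group averages all unordered pairs inside it, and the
#' between mean of two groups averages all cross pairs. Singleton groups
#' have no within pairs; their within mean is reported `NA` (never 0)
#' and flagged in `n_pairs = 0`.
#'
#' @param D a `pdist_matrix` from [distance_matrix()], or a named
#'   symmetric numeric matrix (any scale; means are on the same scale).
#' @param groups data.frame with columns `seq_id` and `group` covering
#'   every ID in the matrix, or a named character vector.
#' @return data.frame with columns `group1`, `group2`, `type`
#'   (`"within"`/`"between"`), `mean_distance`, `n_pairs`.
#' @examples
#' fam <- simulate_divergent_family(
#'   clade_scenario(c(3, 3), 1000, 0.01, 0.2), seed = 5)
#' D <- distance_matrix(fam$sequences)
#' group_mean_distances(D, fam$groups)
#' @export
group_mean_distances <- function(D, groups) {
  d <- as_dist_matrix(D)
  ids <- rownames(d)
  if (is.data.frame(groups)) {
    stopifnot(all(c("seq_id", "group") %in% names(groups)))
    lab <- setNames(as.character(groups$group), groups$seq_id)
  } else {
    lab <- groups
  }
  missing <- setdiff(ids, names(lab))
  if (length(missing)) {
    stop("unlabeled sequence ID(s): ", paste(missing, collapse = ", "))
  }
  g <- lab[ids]
  lev <- unique(g)
  rows <- list()
  for (i in seq_along(lev)) {
    gi <- which(g == lev[i])
    # within
    if (length(gi) >= 2L) {
      sub <- d[gi, gi, drop = FALSE]
      vals <- sub[lower.tri(sub)]
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[i], type = "within",
        mean_distance = mean(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[i], type = "within",
        mean_distance = NA_real_, n_pairs = 0L, stringsAsFactors = FALSE)
    }
    if (i < length(lev)) {
      for (j in (i + 1L):length(lev)) {
        gj <- which(g == lev[j])
        sub <- d[gi, gj, drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = lev[i], group2 = lev[j], type = "between",
          mean_distance = mean(sub), n_pairs = length(sub),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
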