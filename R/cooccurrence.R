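#' Define an anchor set for one virus
#'
#' The anchor transcripts of a virus are its RdRp-confirmed conserved
#' sequences: transcript clusters whose BLAST/DIAMOND hits carry a
#' complete RdRp domain. A sample is *anchor-positive* for the virus if it
#' contains at least one anchor transcript; partial and complete anchor
#' sequences both count as detections.
#'
#' @param virus_id virus label.
#' @param anchor_transcripts nonempty character vector of transcript IDs.
#' @return an object of class `anchor_set`.
#' @export
anchor_set <- function(virus_id, anchor_transcripts) {
  anchor_transcripts <- unique(as.character(anchor_transcripts))
  if (length(anchor_transcripts) == 0L) stop("anchor set must be nonempty")
  structure(list(virus_id = as.character(virus_id),
                 anchor_transcripts = anchor_transcripts),
            class = "anchor_set")
}

# Indicator of anchor-positive samples; errors if none or if an anchor is
# missing from the matrix.
anchor_positive <- function(anchors, matrix) {
  check_presence_matrix(matrix)
  if (!inherits(anchors, "anchor_set")) {
    anchors <- anchor_set("virus", anchors)
  }
  missing <- setdiff(anchors$anchor_transcripts, colnames(matrix))
  if (length(missing)) {
    stop("anchor transcript(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  a <- rowSums(matrix[, anchors$anchor_transcripts, drop = FALSE]) > 0
  if (!any(a)) stop("no anchor-positive samples")
  a
}

#' Co-occurrence recall of a transcript against a virus anchor (V_co)
#'
#' `V_co = |S intersect A| / |A|`: the fraction of anchor-positive
#' samples (samples containing at least one RdRp-confirmed anchor
#' transcript of the virus) that also contain the candidate transcript. A
#' genuine genome segment of the virus should be found in most samples
#' where the virus replicates, so high `V_co` is evidence of segmenthood.
#'
#' @param transcript transcript (cluster) ID present in the matrix.
#' @param anchors an [anchor_set()] (or character vector of anchor IDs).
#' @param matrix 0/1 presence matrix, samples in rows, transcripts in
#'   columns (see [simulate_presence_matrix()], [build_presence_matrix()]).
#' @return fraction in `[0, 1]`.
#' @examples
#' m <- rbind(s1 = c(rdrp = 1L, cand = 1L), s2 = c(1L, 0L), s3 = c(0L, 1L))
#' v_co("cand", "rdrp", m)  # in 1 of the 2 anchor-positive samples
#' @export
v_co <- function(transcript, anchors, matrix) {
  a <- anchor_positive(anchors, matrix)
  if (!transcript %in% colnames(matrix)) {
    stop("unknown transcript ID: ", transcript)
  }
  s <- matrix[, transcript] > 0
  sum(s & a) / sum(a)
}

#' Co-occurrence precision of a transcript against a virus anchor (T_co)
#'
#' `T_co = |S intersect A| / |S|`: the fraction of the transcript's
#' occurrences that are in anchor-positive samples. `T_co = 1` means the
#' transcript is never found without the virus's conserved sequence; low
#' `T_co` flags transcripts (e.g. host or commensal sequences) that also
#' occur where the virus is absent.
#'
#' @inheritParams v_co
#' @return fraction in `[0, 1]`.
#' @export
t_co <- function(transcript, anchors, matrix) {
  a <- anchor_positive(anchors, matrix)
  if (!transcript %in% colnames(matrix)) {
    stop("unknown transcript ID: ", transcript)
  }
  s <- matrix[, transcript] > 0
  if (!any(s)) stop("undefined T_co: transcript never observed")
  sum(s & a) / sum(s)
}

#' Thresholds of the candidate-segment screen
#'
#' Defaults are the screen used for multipartite segment discovery:
#' `V_co >= 0.75`, `T_co >= 0.5`, and a maximum ORF strictly longer than
#' 500 nt (a genome segment must encode a substantial protein).
#'
#' @param v_threshold minimum `V_co` (inclusive), in `[0, 1]`.
#' @param t_threshold minimum `T_co` (inclusive), in `[0, 1]`.
#' @param min_orf_len ORF length bound in nt, exclusive (`> min_orf_len`).
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(v_threshold = 0.75, t_threshold = 0.5,
                          min_orf_len = 500L) {
  stopifnot(v_threshold >= 0, v_threshold <= 1,
            t_threshold >= 0, t_threshold <= 1, min_orf_len >= 0)
  structure(list(v_threshold = v_threshold, t_threshold = t_threshold,
                 min_orf_len = as.integer(min_orf_len)),
            class = "screen_config")
}

#' Screen transcripts for candidate viral genome segments
#'
#' Scores every non-anchor transcript of a presence matrix against a
#' virus's anchor set and calls candidates that satisfy
#' `V_co >= v_threshold`, `T_co >= t_threshold` and
#' `max ORF > min_orf_len` nt. Transcripts never observed in any sample
#' are reported with `passes = FALSE` and flagged rather than aborting
#' the screen; transcripts missing from `orf_lengths` are treated as
#' having ORF length 0 (and counted in a message).
#'
#' @inheritParams v_co
#' @param orf_lengths named numeric vector mapping transcript ID to its
#'   maximum ORF length in nt (see [max_orf_lengths()]).
#' @param config a [screen_config()].
#' @return data.frame with columns `transcript_id`, `v_co`, `t_co`,
#'   `max_orf_len`, `passes`, `note`, sorted by `v_co` then `t_co`
#'   descending, ties broken by transcript ID.
#' @examples
#' sim <- simulate_presence_matrix(
#'   30, list(virus_spec("v1", 2, prevalence = 0.5, fidelity = 0.95)),
#'   n_background = 10, bg_rate = 0.2, seed = 42)
#' orfs <- setNames(rep(1000, ncol(sim$matrix)), colnames(sim$matrix))
#' head(screen_candidates(sim$matrix, anchor_set("v1", "v1_seg1"), orfs))
#' @export
screen_candidates <- function(matrix, anchors, orf_lengths,
                              config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  a <- anchor_positive(anchors, matrix)
  if (!inherits(anchors, "anchor_set")) anchors <- anchor_set("virus", anchors)
  candidates <- setdiff(colnames(matrix), anchors$anchor_transcripts)

  missing_orf <- setdiff(candidates, names(orf_lengths))
  if (length(missing_orf)) {
    message(length(missing_orf),
            " transcript(s) without an ORF length; treated as 0")
  }

  n_a <- sum(a)
  rows <- lapply(candidates, function(tr) {
    s <- matrix[, tr] > 0
    hits <- sum(s & a)
    v <- hits / n_a
    orf <- if (tr %in% names(orf_lengths)) as.numeric(orf_lengths[[tr]]) else 0
    if (!any(s)) {
      data.frame(transcript_id = tr, v_co = 0, t_co = NA_real_,
                 max_orf_len = orf, passes = FALSE, note = "never_observed",
                 stringsAsFactors = FALSE)
    } else {
      t <- hits / sum(s)
      data.frame(transcript_id = tr, v_co = v, t_co = t, max_orf_len = orf,
                 passes = v >= config$v_threshold && t >= config$t_threshold &&
                   orf > config$min_orf_len,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), v_co = numeric(),
                      t_co = numeric(), max_orf_len = numeric(),
                      passes = logical(), note = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$v_co, -ifelse(is.na(out$t_co), -Inf, out$t_co),
                   out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact pass probability of an independently occurring transcript
#'
#' Closed-form binomial computation of the probability that a transcript
#' occurring independently in every sample with probability `rate` (a
#' background transcript, or a companion segment with `rate = fidelity`
#' in carriers / `rate = spillover` elsewhere) satisfies the
#' `V_co`/`T_co` thresholds, marginalised over the carrier count
#' `|A| ~ Binomial(n_samples, prevalence)` (conditioning on `|A| >= 1`,
#' without which the metrics are undefined). Used as the analytic
#' reference for false-positive and recovery rates of the screen on
#' [simulate_presence_matrix()] output.
#'
#' @param n_samples number of samples.
#' @param prevalence carrier probability per sample.
#' @param rate_carrier detection probability in anchor-positive samples.
#' @param rate_noncarrier detection probability in anchor-negative samples.
#' @param config a [screen_config()] (ORF bound ignored here).
#' @return probability that the transcript passes the `V_co`/`T_co` part
#'   of the screen.
#' @export
screen_pass_probability <- function(n_samples, prevalence,
                                    rate_carrier, rate_noncarrier,
                                    config = screen_config()) {
  n <- as.integer(n_samples)
  pa <- stats::dbinom(0:n, n, prevalence)
  p_given_a <- vapply(0:n, function(a) {
    if (a == 0L) return(0)
    px <- stats::dbinom(0:a, a, rate_carrier)
    py <- stats::dbinom(0:(n - a), n - a, rate_noncarrier)
    tot <- 0
    for (x in 0:a) {
      if (x / a < config$v_threshold) next
      for (y in 0:(n - a)) {
        if (x + y == 0L) next
        if (x / (x + y) >= config$t_threshold) tot <- tot + px[x + 1] * py[y + 1]
      }
    }
    tot
  }, numeric(1))
  sum(pa * p_given_a) / (1 - pa[1])
}
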