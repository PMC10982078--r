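#' Specify a simulated multipartite virus
#'
#' Describes one multi-segment virus for [simulate_presence_matrix()]. A
#' sample "carries" the virus with probability `prevalence`; in carrier
#' samples the anchor segment (the RdRp-bearing conserved sequence) is
#' always detected, each other segment is detected with probability
#' `fidelity`, and in non-carrier samples each non-anchor segment shows up
#' spuriously with probability `spillover` (index bleed, misassembly,
#' contamination).
#'
#' @param virus_id label used to name the segment columns.
#' @param n_segments number of genome segments (>= 1).
#' @param prevalence probability in `(0, 1]` that a sample carries the virus.
#' @param fidelity probability in `(0, 1]` that a non-anchor segment is
#'   detected in a carrier sample.
#' @param spillover probability in `[0, 1)` that a non-anchor segment is
#'   detected in a non-carrier sample.
#' @param anchor_segment 1-based index of the anchor segment.
#' @return an object of class `virus_spec`.
#' @examples
#' virus_spec("tenui1", n_segments = 3, prevalence = 0.4, fidelity = 0.9)
#' @export
virus_spec <- function(virus_id, n_segments, prevalence, fidelity,
                       spillover = 0, anchor_segment = 1L) {
  stopifnot(is.character(virus_id), length(virus_id) == 1L, nzchar(virus_id))
  n_segments <- as.integer(n_segments)
  anchor_segment <- as.integer(anchor_segment)
  if (is.na(n_segments) || n_segments < 1L) stop("n_segments must be >= 1")
  if (anchor_segment < 1L || anchor_segment > n_segments) {
    stop("anchor_segment must be in [1, n_segments]")
  }
  if (!(prevalence > 0 && prevalence <= 1)) stop("prevalence must be in (0, 1]")
  if (!(fidelity > 0 && fidelity <= 1)) stop("fidelity must be in (0, 1]")
  if (!(spillover >= 0 && spillover < 1)) stop("spillover must be in [0, 1)")
  structure(list(virus_id = virus_id, n_segments = n_segments,
                 anchor_segment = anchor_segment, prevalence = prevalence,
                 fidelity = fidelity, spillover = spillover),
            class = "virus_spec")
}

#' Simulate a sample-by-transcript presence/absence matrix
#'
#' Generates the substrate of the co-occurrence screen: a 0/1 matrix whose
#' columns are the segments of one or more simulated multipartite viruses
#' plus independently occurring background transcripts, together with a
#' truth table labelling every column. Carrier status is drawn per virus
#' independently per sample; segment detections are conditionally
#' independent given carrier status; the anchor column equals the carrier
#' indicator exactly.
#'
#' @param n_samples number of samples (rows), >= 1.
#' @param viruses list of [virus_spec()] objects (may be empty if
#'   `n_background > 0`).
#' @param n_background number of background transcript columns.
#' @param bg_rate per-sample detection probability of a background
#'   transcript, in `[0, 1]`.
#' @param seed integer seed (required; same seed, same output).
#' @return a list with components `matrix` (integer 0/1 matrix, samples in
#'   rows) and `truth` (data.frame: `transcript_id`, `role` one of
#'   `"anchor"`, `"companion"`, `"background"`, `virus_id`, `segment`).
#' @examples
#' sim <- simulate_presence_matrix(
#'   20, list(virus_spec("v1", 2, prevalence = 0.5, fidelity = 0.9)),
#'   n_background = 5, bg_rate = 0.2, seed = 1)
#' colSums(sim$matrix)
#' @export
simulate_presence_matrix <- function(n_samples, viruses = list(),
                                     n_background = 0L, bg_rate = 0.1,
                                     seed) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("empty design: n_samples must be >= 1")
  n_background <- as.integer(n_background)
  if (n_background < 0L) stop("n_background must be >= 0")
  if (length(viruses) == 0L && n_background == 0L) stop("nothing to simulate")
  if (!(bg_rate >= 0 && bg_rate <= 1)) stop("bg_rate must be in [0, 1]")
  for (v in viruses) {
    if (!inherits(v, "virus_spec")) stop("viruses must be a list of virus_spec objects")
  }

  with_seed(seed, {
    samples <- sprintf("sample_%02d", seq_len(n_samples))
    cols <- list()
    truth <- list()
    for (v in viruses) {
      carrier <- runif(n_samples) < v$prevalence
      for (s in seq_len(v$n_segments)) {
        id <- sprintf("%s_seg%d", v$virus_id, s)
        if (s == v$anchor_segment) {
          col <- as.integer(carrier)
          role <- "anchor"
        } else {
          col <- integer(n_samples)
          col[carrier] <- as.integer(runif(sum(carrier)) < v$fidelity)
          col[!carrier] <- as.integer(runif(sum(!carrier)) < v$spillover)
          role <- "companion"
        }
        cols[[id]] <- col
        truth[[id]] <- data.frame(transcript_id = id, role = role,
                                  virus_id = v$virus_id, segment = s,
                                  stringsAsFactors = FALSE)
      }
    }
    if (n_background > 0L) {
      for (b in seq_len(n_background)) {
        id <- sprintf("bg_%04d", b)
        cols[[id]] <- as.integer(runif(n_samples) < bg_rate)
        truth[[id]] <- data.frame(transcript_id = id, role = "background",
                                  virus_id = NA_character_, segment = NA_integer_,
                                  stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- samples
    list(matrix = m, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Specify a two-or-more-clade divergence scenario
#'
#' Parameters for [simulate_divergent_family()]: clade sizes, sequence
#' length and per-site substitution probabilities within each clade
#' (ancestor to tip) and between the root and each clade ancestor.
#'
#' @param n_per_clade integer vector of clade sizes (one entry per clade).
#' @param seq_len sequence length in nt, > 0.
#' @param within_divergence per-site substitution probability on each
#'   ancestor-to-tip branch; scalar or one value per clade; in `[0, 1)`.
#' @param between_divergence per-site substitution probability on each
#'   root-to-clade-ancestor branch; in `[0, 1)`.
#' @return an object of class `clade_scenario`.
#' @export
clade_scenario <- function(n_per_clade, seq_len, within_divergence,
                           between_divergence) {
  n_per_clade <- as.integer(n_per_clade)
  if (length(n_per_clade) < 1L || any(n_per_clade < 1L)) {
    stop("n_per_clade must be positive integers")
  }
  seq_len <- as.integer(seq_len)
  if (is.na(seq_len) || seq_len < 1L) stop("seq_len must be > 0")
  k <- length(n_per_clade)
  within_divergence <- rep_len(within_divergence, k)
  if (any(within_divergence < 0 | within_divergence >= 1) ||
      between_divergence < 0 || between_divergence >= 1) {
    stop("divergences must be in [0, 1)")
  }
  structure(list(n_per_clade = n_per_clade, seq_len = seq_len,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence),
            class = "clade_scenario")
}

# Mutate each site with probability p, replacing it by one of the three
# alternative bases uniformly (no rate heterogeneity, no indels).
mutate_sites <- function(seq_vec, p, bases = c("A", "C", "G", "T")) {
  hit <- which(runif(length(seq_vec)) < p)
  if (length(hit)) {
    seq_vec[hit] <- vapply(seq_vec[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  seq_vec
}

#' Expected p-distance between two simulated tips
#'
#' Closed-form per-site mismatch probability for tips of
#' [simulate_divergent_family()]. Each branch applies independent
#' per-site substitution to one of the three alternative bases; a branch
#' with substitution probability `p` has spectral factor
#' `lambda = 1 - 4p/3`, factors multiply along the path joining two tips,
#' and the mismatch probability is `3/4 * (1 - prod(lambda))`.
#'
#' @param branch_probs numeric vector of per-branch substitution
#'   probabilities along the path between the two tips (e.g.
#'   `c(w, w)` for a within-clade pair, `c(w, b, b, w)` for a
#'   between-clade pair).
#' @return the expected p-distance (per-site mismatch probability).
#' @examples
#' expected_p_distance(c(0.03, 0.03))  # within-clade pair at 3% divergence
#' @export
expected_p_distance <- function(branch_probs) {
  stopifnot(all(branch_probs >= 0 & branch_probs < 1))
  0.75 * (1 - prod(1 - 4 * branch_probs / 3))
}

#' Simulate a sequence family with clade structure
#'
#' Generates equal-length ungapped nucleotide sequences from a star-like
#' two-level model: a uniform-random root sequence, one ancestor per clade
#' derived from the root by per-site substitution at
#' `between_divergence`, and tips derived from their clade ancestor at
#' `within_divergence`. Substitutions pick uniformly among the three
#' alternative bases. Intended as input for [distance_matrix()] and
#' [group_mean_distances()]; [expected_p_distance()] gives the matching
#' closed-form pairwise expectations.
#'
#' @param scenario a [clade_scenario()].
#' @param seed integer seed.
#' @return list with `sequences` (named character vector, names like
#'   `clade1_seq01`) and `groups` (data.frame `seq_id`, `group`).
#' @examples
#' fam <- simulate_divergent_family(
#'   clade_scenario(c(3, 3), seq_len = 1000,
#'                  within_divergence = 0.02, between_divergence = 0.2),
#'   seed = 7)
#' fam$groups
#' @export
simulate_divergent_family <- function(scenario, seed) {
  stopifnot(inherits(scenario, "clade_scenario"))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, scenario$seq_len, replace = TRUE)
    seqs <- character(0)
    ids <- character(0)
    groups <- character(0)
    for (k in seq_along(scenario$n_per_clade)) {
      anc <- mutate_sites(root, scenario$between_divergence, bases)
      for (i in seq_len(scenario$n_per_clade[k])) {
        tip <- mutate_sites(anc, scenario$within_divergence[k], bases)
        id <- sprintf("clade%d_seq%02d", k, i)
        seqs <- c(seqs, paste(tip, collapse = ""))
        ids <- c(ids, id)
        groups <- c(groups, sprintf("clade%d", k))
      }
    }
    names(seqs) <- ids
    list(sequences = seqs,
         groups = data.frame(seq_id = ids, group = groups,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate a per-sample virus/Wolbachia read-percentage table
#'
#' Draws an abundance table with a known linear relationship
#' `pct_virus = intercept + slope * pct_wolbachia + N(0, noise_sd)`,
#' truncated at zero after noise is added (read percentages cannot be
#' negative; with `noise_sd = 0` and non-negative fitted values the
#' truncation is inert and the generating line is recovered exactly).
#'
#' @param n number of samples, >= 3.
#' @param slope,intercept generating line.
#' @param noise_sd standard deviation of Gaussian noise, >= 0.
#' @param x_values optional predictor values (per-sample Wolbachia read
#'   percentages); defaults to `runif(n, 0, 5)`, the magnitude typical of
#'   endosymbiont read fractions. Must not be constant.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `pct_virus`, `pct_wolbachia`.
#' @examples
#' simulate_abundance_table(3, slope = 2, intercept = 1, noise_sd = 0,
#'                          x_values = c(0, 1, 2), seed = 1)
#' @export
simulate_abundance_table <- function(n, slope, intercept, noise_sd,
                                     x_values = NULL, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("degenerate regression design: n must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    x <- if (is.null(x_values)) runif(n, 0, 5) else as.numeric(x_values)
    if (length(x) != n) stop("x_values must have length n")
    if (any(x < 0)) stop("x_values must be non-negative")
    if (isTRUE(all.equal(max(x), min(x)))) stop("constant x: predictor has zero variance")
    y <- intercept + slope * x + rnorm(n, 0, noise_sd)
    y <- pmax(y, 0)
    data.frame(sample = sprintf("sample_%02d", seq_len(n)),
               pct_virus = y, pct_wolbachia = x,
               stringsAsFactors = FALSE)
  })
}

# 12-nt block carrying a stop codon in all six reading frames:
# forward frames hit TAG, reverse-complement frames (CTAACTAACTAA) hit TAA.
.stop_block <- "TTAGTTAGTTAG"

#' Simulate a transcript with implanted ORFs of known coordinates
#'
#' Builds a nucleotide sequence containing start-to-stop ORFs of the
#' requested lengths at the requested frames, separated by spacers that
#' carry stop codons in all six frames, so no stop-free run in any frame
#' spans more than one implant and an implanted ORF is never extended or
#' subsumed by a longer same-frame ORF. ORF interiors are drawn from
#' `{C,G}`-only codons:
#' those contain no `A` or `T` on either strand, so no spurious `ATG` or
#' stop can arise inside or across an implant and a start-to-stop scan
#' recovers exactly the implanted ORFs. (Stop-to-stop scans additionally
#' report the incidental stop-free runs every sequence has.)
#'
#' @param orf_lengths ORF lengths in nt, each >= 6 and divisible by 3
#'   (length excludes the terminating stop codon).
#' @param frames frame labels, one per ORF, integers in
#'   `{1, 2, 3, -1, -2, -3}` (positive = forward strand).
#' @param spacer_len nominal spacer length in nt; spacers are extended to
#'   at least 12 nt so every frame sees a stop between implants.
#' @param seed integer seed.
#' @return list with `sequence` (nucleotide string) and `truth`
#'   (data.frame `frame`, `start`, `end`, `length_nt`, `nt_seq`, `aa_seq`;
#'   coordinates 0-based half-open on the forward strand, as in
#'   [find_orfs()]).
#' @examples
#' tx <- simulate_transcript_with_orfs(9, frames = 1, seed = 1)
#' find_orfs(tx$sequence, mode = "start_to_stop_nt", min_len = 9)
#' @export
simulate_transcript_with_orfs <- function(orf_lengths, frames,
                                          spacer_len = 24L, seed) {
  orf_lengths <- as.integer(orf_lengths)
  frames <- as.integer(frames)
  if (length(orf_lengths) != length(frames)) {
    stop("orf_lengths and frames must have the same length")
  }
  if (any(orf_lengths < 6L) || any(orf_lengths %% 3L != 0L)) {
    stop("each ORF length must be >= 6 nt and divisible by 3")
  }
  if (!all(frames %in% c(1L, 2L, 3L, -1L, -2L, -3L))) {
    stop("frames must be in {1, 2, 3, -1, -2, -3}")
  }
  spacer_len <- max(as.integer(spacer_len), 0L)

  spacer <- function(min_nt) {
    n <- max(min_nt, 12L)
    substr(strrep(.stop_block, ceiling(n / 12) + 1L), 1L, n)
  }
  safe_codons <- c("CCC", "CCG", "CGC", "CGG", "GCC", "GCG", "GGC", "GGG")

  with_seed(seed, {
    parts <- spacer(spacer_len)
    pos <- nchar(parts)              # forward 0-based cursor
    truth <- list()
    seq_parts <- parts
    for (i in seq_along(orf_lengths)) {
      len <- orf_lengths[i]
      fr <- frames[i]
      nt <- paste0("ATG",
                   paste(sample(safe_codons, len / 3L - 1L, replace = TRUE),
                         collapse = ""))
      insert <- paste0(nt, "TAA")    # ORF plus its terminating stop
      if (fr > 0L) {
        # want start pos s with s %% 3 == fr - 1
        pad <- (fr - 1L - pos) %% 3L
        s <- pos + pad
        rec <- list(frame = fr, start = s, end = s + len, nt = nt)
      } else {
        # implant the reverse complement; frame fixed after final padding
        # to total length L with L %% 3 == 0: need (L - e) %% 3 == -fr - 1,
        # i.e. e %% 3 == (fr + 1) %% 3 where e is the forward end of the
        # ORF proper (which begins after the implanted TAA complement).
        insert <- reverse_complement(insert)  # TTA + rc(nt)
        want_e <- (fr + 1L) %% 3L
        # forward layout: [pad][TTA][rc(nt)]; ORF slice = [s, e) with
        # s = pos + pad + 3, e = s + len
        pad <- (want_e - (pos + 3L + len)) %% 3L
        s <- pos + pad + 3L
        rec <- list(frame = fr, start = s, end = s + len, nt = nt)
      }
      pad_str <- strrep("T", (rec$start - if (fr > 0L) 0L else 3L) - pos)
      seq_parts <- paste0(seq_parts, pad_str, insert)
      pos <- nchar(seq_parts)
      truth[[i]] <- rec
      gap <- spacer(spacer_len)
      seq_parts <- paste0(seq_parts, gap)
      pos <- nchar(seq_parts)
    }
    # pad total length to a multiple of 3 so minus-strand frames land as
    # computed above
    tail_pad <- (3L - pos %% 3L) %% 3L
    seq_parts <- paste0(seq_parts, strrep("T", tail_pad))

    truth_df <- do.call(rbind, lapply(truth, function(r) {
      data.frame(frame = r$frame, start = r$start, end = r$end,
                 length_nt = nchar(r$nt), nt_seq = r$nt,
                 aa_seq = translate_nt(r$nt), stringsAsFactors = FALSE)
    }))
    truth_df <- truth_df[order(truth_df$start, match(truth_df$frame,
                                                     c(1, 2, 3, -1, -2, -3))), ,
                         drop = FALSE]
    rownames(truth_df) <- NULL
    list(sequence = seq_parts, truth = truth_df)
  })
}
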