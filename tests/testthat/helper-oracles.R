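# Independent brute-force oracles; deliberately naive, written against the
# documented semantics rather than the implementation.

# Six-frame ORF scan as an explicit state machine. Walks every frame
# codon by codon; returns the same columns as find_orfs().
brute_orfs <- function(seq, start_required = FALSE, min_len = 0L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  revcomp <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  is_stop <- function(cd) cd %in% c("TAA", "TAG", "TGA")
  out <- list()
  for (sgn in c(1L, -1L)) {
    s <- if (sgn == 1L) seq else revcomp(seq)
    for (off in 0:2) {
      pos <- off + 1L
      run_start <- NA_integer_   # 1-based nt position of current run start
      open <- !start_required
      cur <- if (open) pos else NA_integer_
      while (pos + 2L <= L) {
        cd <- substr(s, pos, pos + 2L)
        if (is_stop(cd)) {
          if (!is.na(cur)) {
            out[[length(out) + 1L]] <- c(sgn, off, cur, pos - 1L)
          }
          cur <- if (start_required) NA_integer_ else pos + 3L
        } else if (start_required && is.na(cur) && cd == "ATG") {
          cur <- pos
        }
        pos <- pos + 3L
      }
      if (!is.na(cur) && pos - 1L >= cur) {
        out[[length(out) + 1L]] <- c(sgn, off, cur, pos - 1L)
      }
    }
  }
  rows <- lapply(out, function(r) {
    sgn <- r[1]; off <- r[2]; a <- r[3]; b <- r[4]
    len <- b - a + 1L
    if (len < max(min_len, 3L)) return(NULL)
    s <- if (sgn == 1L) seq else revcomp(seq)
    nt <- substr(s, a, b)
    if (sgn == 1L) {
      st <- a - 1L; en <- b
    } else {
      st <- L - b; en <- L - a + 1L
    }
    data.frame(frame = sgn * (off + 1L), start = st, end = en,
               length_nt = len, nt_seq = nt, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), nt_seq = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res[order(res$start, match(res$frame, c(1, 2, 3, -1, -2, -3))), ,
      drop = FALSE]
}

# Set-intersection counts for the co-occurrence metrics.
brute_cooc <- function(m, anchor_ids, transcript) {
  A <- rownames(m)[apply(m[, anchor_ids, drop = FALSE] == 1L, 1L, any)]
  S <- rownames(m)[m[, transcript] == 1L]
  list(v = length(intersect(S, A)) / length(A),
       t = if (length(S)) length(intersect(S, A)) / length(S) else NA_real_)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small presence matrix from explicit columns.
pm <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, lapply(cols, as.integer))
  colnames(m) <- names(cols)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  m
}

# Joint probability that all companions of a virus pass the V/T screen,
# marginalised over the carrier count (companions are conditionally
# independent given the carrier set).
joint_companion_pass_prob <- function(n, prevalence, fidelity, spillover,
                                      n_companions,
                                      config = cimexvir::screen_config()) {
  pa <- dbinom(0:n, n, prevalence)
  p1 <- vapply(0:n, function(a) {
    if (a == 0) return(0)
    px <- dbinom(0:a, a, fidelity)
    py <- dbinom(0:(n - a), n - a, spillover)
    tot <- 0
    for (x in 0:a) {
      if (x / a < config$v_threshold) next
      for (y in 0:(n - a)) {
        if (x + y == 0) next
        if (x / (x + y) >= config$t_threshold) tot <- tot + px[x + 1] * py[y + 1]
      }
    }
    tot
  }, numeric(1))
  sum(pa * p1^n_companions) / (1 - pa[1])
}
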