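test_that("within-sample duplicates are discarded, cross-sample duplicates kept", {
  d <- data.frame(sample = c("a", "a", "b", "a"),
                  sequence = c("ACGT", "ACGT", "ACGT", "TTTT"),
                  stringsAsFactors = FALSE)
  out <- dedupe_within_sample(d)
  expect_equal(nrow(out), 3L)
  expect_equal(out$sample, c("a", "b", "a"))
  # case-folded comparison
  d2 <- data.frame(sample = c("a", "a"), sequence = c("acgt", "ACGT"))
  expect_equal(nrow(dedupe_within_sample(d2)), 1L)
})

test_that("p_distance counts mismatches over pairwise-deleted sites", {
  expect_equal(p_distance("ACGT", "ACGT")$distance, 0)
  expect_equal(p_distance("AAAA", "TTTT")$distance, 1)
  pd <- p_distance("A-CGT", "AACGA")
  expect_equal(pd$distance, 0.25)
  expect_equal(pd$sites, 4L)
  # N excludes a site just like a gap
  expect_equal(p_distance("ANCG", "AACG")$sites, 3L)
  expect_error(p_distance("----", "AAAA"), "no comparable sites")
  expect_error(p_distance("AC", "ACG"), "equal length")
})

test_that("distance_matrix matches a hand-built fixture and is structurally valid", {
  aln <- c(x = "AAAAAA", y = "AAATTT", z = "TTTTTT")
  D <- distance_matrix(aln)
  expect_equal(D$d["x", "y"], 0.5)
  expect_equal(D$d["x", "z"], 1)
  expect_equal(D$d["y", "z"], 0.5)
  expect_true(isSymmetric(D$d))
  expect_true(all(diag(D$d) == 0))
  expect_true(all(D$d >= 0 & D$d <= 1))
})

test_that("pairwise and complete deletion policies differ as documented", {
  aln <- c(x = "A-AAT", y = "AAAAA", z = "AAAAC")
  # pairwise: x/y compared at 4 sites, y/z at all 5
  Dp <- distance_matrix(aln, policy = "pairwise_deletion")
  expect_equal(Dp$sites["x", "y"], 4L)
  expect_equal(Dp$sites["y", "z"], 5L)
  expect_equal(Dp$d["y", "z"], 0.2)
  # complete: the gapped column 2 is dropped for every pair
  Dc <- distance_matrix(aln, policy = "complete_deletion")
  expect_true(all(Dc$sites == 4L))
  expect_equal(Dc$d["y", "z"], 0.25)
})

test_that("pairwise-deletion distances agree with ape on gapped alignments", {
  skip_if_not_installed("ape")
  set.seed(15)
  for (rep in 1:5) {
    fam <- simulate_divergent_family(
      clade_scenario(c(3, 3), 300, within_divergence = 0.05,
                     between_divergence = 0.2), seed = 40 + rep)
    seqs <- fam$sequences
    # punch random gaps/Ns into the alignment
    for (i in seq_along(seqs)) {
      s <- strsplit(seqs[[i]], "")[[1]]
      s[sample(length(s), 10)] <- "-"
      s[sample(length(s), 5)] <- "N"
      seqs[[i]] <- paste(s, collapse = "")
    }
    D <- distance_matrix(seqs)$d
    bin <- ape::as.DNAbin(lapply(seqs, function(s) {
      tolower(strsplit(s, "")[[1]])
    }))
    ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
    expect_equal(unname(D), unname(ref[rownames(D), colnames(D)]),
                 tolerance = 1e-12)
  }
})

test_that("group means: singletons are NA, identical groups are 0, errors on unlabeled IDs", {
  aln <- c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT")
  D <- distance_matrix(aln)
  g <- data.frame(seq_id = c("a1", "a2", "b1"), group = c("A", "A", "B"))
  gm <- group_mean_distances(D, g)
  expect_equal(gm$mean_distance[gm$group1 == "A" & gm$type == "within"], 0)
  wB <- gm[gm$group1 == "B" & gm$type == "within", ]
  expect_true(is.na(wB$mean_distance))
  expect_equal(wB$n_pairs, 0L)
  expect_error(group_mean_distances(D, g[1:2, ]), "unlabeled")
})

test_that("group means are invariant to sequence order and satisfy the grand-mean identity", {
  set.seed(90)
  for (rep in 1:10) {
    k <- 8
    d <- matrix(0, k, k)
    d[lower.tri(d)] <- runif(k * (k - 1) / 2)
    d <- d + t(d)
    ids <- sprintf("q%d", 1:k)
    dimnames(d) <- list(ids, ids)
    g <- data.frame(seq_id = ids,
                    group = sample(c("g1", "g2", "g3"), k, replace = TRUE))
    if (length(unique(g$group)) < 2) next
    gm <- group_mean_distances(d, g)
    # permutation invariance
    perm <- sample(k)
    gm2 <- group_mean_distances(d[perm, perm], g)
    # between-pair labels may appear swapped after permutation
    key <- function(x) {
      x$pair <- paste(pmin(x$group1, x$group2), pmax(x$group1, x$group2))
      x[order(x$pair), ]
    }
    expect_equal(key(gm)$mean_distance, key(gm2)$mean_distance)
    # grand mean = pair-count-weighted mean of the group summaries
    ok <- !is.na(gm$mean_distance)
    grand <- sum(gm$mean_distance[ok] * gm$n_pairs[ok]) / sum(gm$n_pairs[ok])
    expect_equal(grand, mean(d[lower.tri(d)]), tolerance = 1e-12)
  }
})

test_that("the packaged tenuivirus matrix reproduces the published clade summaries", {
  ref <- tenuivirus_reference_distances()
  gm <- group_mean_distances(ref$d, ref$groups)
  pick <- function(g1, g2, type) {
    r <- gm[gm$type == type &
              ((gm$group1 == g1 & gm$group2 == g2) |
                 (gm$group1 == g2 & gm$group2 == g1)), ]
    100 * r$mean_distance
  }
  expect_equal(pick("Italy", "Italy", "within"), 3.0, tolerance = 0.05 / 3.0)
  expect_lt(abs(pick("Rest of the World", "Rest of the World", "within") - 1.1), 0.05)
  expect_lt(abs(pick("Outgroup", "Outgroup", "within") - 36.5), 0.05)
  expect_lt(abs(pick("Italy", "Outgroup", "between") - 55.8), 0.05)
  expect_lt(abs(pick("Rest of the World", "Outgroup", "between") - 55.9), 0.05)
  # the Italy-vs-rest cell recomputed from the rounded printed matrix lands
  # near 22.25, not the published 22.4 (which used unrounded distances)
  expect_lt(abs(pick("Italy", "Rest of the World", "between") - 22.25), 0.05)
})

test_that("percent formatting rounds half away from zero to one decimal", {
  expect_equal(format_pct(0.22253), "22.3%")
  expect_equal(format_pct(0.03), "3.0%")
  expect_equal(format_pct(0.00045), "0.0%")
  expect_equal(format_pct(0.00055), "0.1%")
  expect_true(is.na(format_pct(NA_real_)))
})
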