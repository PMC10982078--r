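test_that("perfect-fidelity virus yields identical anchor and companion columns", {
  sim <- simulate_presence_matrix(
    10, list(virus_spec("v", 2, prevalence = 1, fidelity = 1, spillover = 0)),
    seed = 1)
  expect_equal(dim(sim$matrix), c(10L, 2L))
  expect_true(all(sim$matrix == 1L))
  expect_equal(v_co("v_seg2", anchor_set("v", "v_seg1"), sim$matrix), 1)
  expect_equal(t_co("v_seg2", anchor_set("v", "v_seg1"), sim$matrix), 1)
  expect_equal(sim$truth$role, c("anchor", "companion"))
})

test_that("presence simulation is deterministic under a seed and rejects empty designs", {
  v <- list(virus_spec("v", 3, prevalence = 0.5, fidelity = 0.8,
                       spillover = 0.05))
  a <- simulate_presence_matrix(25, v, n_background = 10, bg_rate = 0.3,
                                seed = 11)
  b <- simulate_presence_matrix(25, v, n_background = 10, bg_rate = 0.3,
                                seed = 11)
  c <- simulate_presence_matrix(25, v, n_background = 10, bg_rate = 0.3,
                                seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$matrix, c$matrix))

  expect_error(simulate_presence_matrix(0, v, seed = 1), "empty design")
  expect_error(simulate_presence_matrix(5, list(), n_background = 0, seed = 1),
               "nothing to simulate")
})

test_that("companion detection frequency matches the fidelity parameter", {
  sim <- simulate_presence_matrix(
    2000, list(virus_spec("v", 2, prevalence = 0.5, fidelity = 0.9,
                          spillover = 0)),
    seed = 7)
  anch <- anchor_set("v", "v_seg1")
  n_a <- sum(sim$matrix[, "v_seg1"])
  v <- v_co("v_seg2", anch, sim$matrix)
  se <- sqrt(0.9 * 0.1 / n_a)
  expect_lt(abs(v - 0.9), 3 * se)
  # spillover 0: companion never occurs outside carriers
  expect_true(all(sim$matrix[, "v_seg2"] <= sim$matrix[, "v_seg1"]))
})

test_that("anchor column equals the carrier indicator and background sums are binomial", {
  # fidelity < 1 but spillover 0: companions are a subset of the anchor
  # column, which is itself the carrier indicator
  sums <- vapply(1:30, function(s) {
    sim <- simulate_presence_matrix(
      40, list(virus_spec("v", 2, prevalence = 0.6, fidelity = 0.7,
                          spillover = 0)),
      n_background = 5, bg_rate = 0.25, seed = 500 + s)
    expect_true(all(sim$matrix[, "v_seg2"] <= sim$matrix[, "v_seg1"]))
    mean(colSums(sim$matrix[, sim$truth$role == "background"]))
  }, numeric(1))
  n_cols <- 30 * 5
  se <- sqrt(0.25 * 0.75 * 40) / sqrt(n_cols)
  expect_lt(abs(mean(sums) - 40 * 0.25), 4 * se)
})

test_that("zero-divergence families are identical and two-clade structure is deterministic per pair", {
  fam0 <- simulate_divergent_family(
    clade_scenario(c(3, 3), 400, within_divergence = 0,
                   between_divergence = 0), seed = 2)
  expect_length(unique(fam0$sequences), 1L)
  D0 <- distance_matrix(fam0$sequences)
  expect_true(all(D0$d == 0))

  fam <- simulate_divergent_family(
    clade_scenario(c(3, 3), 2000, within_divergence = 0,
                   between_divergence = 0.2), seed = 3)
  D <- distance_matrix(fam$sequences)
  g <- fam$groups$group
  within <- D$d[g == "clade1", g == "clade1"]
  across <- D$d[g == "clade1", g == "clade2"]
  expect_true(all(within == 0))
  expect_length(unique(as.vector(across)), 1L)
})

test_that("simulated within-clade distances match the closed-form mismatch probability", {
  q <- 0.03
  expected <- expected_p_distance(c(q, q))
  means <- vapply(1:12, function(s) {
    fam <- simulate_divergent_family(
      clade_scenario(c(4, 4), 5000, within_divergence = q,
                     between_divergence = 0.15), seed = 100 + s)
    gm <- group_mean_distances(distance_matrix(fam$sequences), fam$groups)
    mean(gm$mean_distance[gm$type == "within"])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("between-divergence exceeding within-divergence separates the group means", {
  ok <- vapply(1:20, function(s) {
    fam <- simulate_divergent_family(
      clade_scenario(c(3, 3), 2000, within_divergence = 0.02,
                     between_divergence = 0.15), seed = s)
    gm <- group_mean_distances(distance_matrix(fam$sequences), fam$groups)
    bet <- gm$mean_distance[gm$type == "between"]
    wit <- gm$mean_distance[gm$type == "within"]
    all(bet > max(wit))
  }, logical(1))
  expect_true(all(ok))
})

test_that("abundance simulation recovers the generating line and rejects degenerate designs", {
  tab <- simulate_abundance_table(3, slope = 2, intercept = 1, noise_sd = 0,
                                  x_values = c(0, 1, 2), seed = 1)
  expect_equal(tab$pct_virus, c(1, 3, 5))
  expect_error(simulate_abundance_table(2, 1, 0, 0, seed = 1), "degenerate")
  expect_error(simulate_abundance_table(5, 1, 0, 0, x_values = rep(2, 5),
                                        seed = 1), "constant x")
  # truncation: a steep negative line cannot produce negative percentages
  tab2 <- simulate_abundance_table(50, slope = -3, intercept = 0.5,
                                   noise_sd = 0.2, seed = 9)
  expect_true(all(tab2$pct_virus >= 0))
})

test_that("fitted slope is unbiased across simulated abundance tables", {
  slopes <- vapply(1:200, function(s) {
    tab <- simulate_abundance_table(22, slope = -0.04, intercept = 0.4,
                                    noise_sd = 0.25,
                                    x_values = seq(0.1, 4.3, length.out = 22),
                                    seed = 2000 + s)
    correlate_abundance(tab)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.04)), 3 * se)
})

test_that("implanted ORFs are recovered exactly by a start-to-stop scan", {
  cases <- list(
    list(len = 9, fr = 1),
    list(len = c(9, 12, 15), fr = c(1, -2, 3)),
    list(len = c(21, 9), fr = c(-1, 2)),
    list(len = c(12, 12, 12), fr = c(-3, -2, -1))
  )
  for (cs in cases) {
    tx <- simulate_transcript_with_orfs(cs$len, frames = cs$fr,
                                        spacer_len = 18, seed = 21)
    got <- find_orfs(tx$sequence, mode = "start_to_stop_nt", min_len = 6)
    expect_equal(got[, c("frame", "start", "end", "length_nt", "nt_seq")],
                 tx$truth[, c("frame", "start", "end", "length_nt", "nt_seq")])
    expect_false(any(grepl("*", tx$truth$aa_seq, fixed = TRUE)))
  }
  expect_error(simulate_transcript_with_orfs(8, frames = 1, seed = 1),
               "divisible by 3")
})
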