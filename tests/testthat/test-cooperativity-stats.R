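# Occupancy histograms, arrangement/adjacency tests, inter-ring and
# conformational statistics.

test_that("occupancy histograms count complete rings and paired particles", {
  occ <- occ_of_patterns(list(c(1, 1, 1, 1, 0, 0, 0, 0)), 10)
  ps <- ps_from_occ(occ)
  h <- occupancy_histogram(ps, "ring")
  expect_equal(h$count[h$k == 4], 10)
  expect_equal(sum(h$count), 10)
  expect_equal(attr(h, "saturation"), 0.5)
  hp <- occupancy_histogram(ps, "particle")
  expect_equal(sum(hp$count), 5)  # 10 rings paired into 5 particles
  expect_equal(hp$count[hp$m == 8], 5)
})

test_that("ring occupancy under independent binding is Binomial(8, p)", {
  ps <- simulate_particle_set(sim_config(5000, binding_model("independent", p = 0.5),
                                         seed = 14))
  h <- occupancy_histogram(ps, "ring")
  pval <- chisq.test(h$count, p = dbinom(0:8, 8, 0.5))$p.value
  expect_gt(pval, 0.01)
})

test_that("a sample exactly at the null gives statistic 0 and p = 1", {
  pats <- list(c(1, 1, 0, 0, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0, 0, 0),
               c(1, 0, 0, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 1, 0, 0, 0))
  ps <- ps_from_occ(occ_of_patterns(pats, c(8, 8, 8, 4)))
  rep <- arrangement_frequencies(ps, 2, seed = 1)
  expect_equal(rep$statistic, 0)
  expect_equal(rep$p_value, 1)
  expect_equal(rep$n_effective, 28L)
  expect_equal(sum(rep$table$proportion), 1)
})

test_that("arrangement proportions track the null under independent binding", {
  ps <- simulate_particle_set(sim_config(2500, binding_model("independent", p = 0.5),
                                         seed = 15))
  rep <- arrangement_frequencies(ps, 2, seed = 16)
  n <- rep$n_effective
  for (i in seq_len(nrow(rep$table))) {
    p0 <- rep$table$null_prob[i]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(rep$table$proportion[i] - p0), 3.5 * se)
  }
  expect_equal(sum(rep$table$observed), n)
})

test_that("sparse strata are reported descriptively without p-values", {
  ps <- ps_from_occ(occ_of_patterns(list(c(1, 1, 0, 0, 0, 0, 0, 0)), 5))
  rep <- arrangement_frequencies(ps, 2, min_stratum = 20)
  expect_true(is.na(rep$p_value))
  expect_equal(rep$n_effective, 5L)
  empty <- arrangement_frequencies(ps, 6)
  expect_equal(empty$n_effective, 0L)
  expect_true(is.na(empty$p_value))
})

test_that("adjacency statistic and its exact null match enumeration", {
  expect_equal(adjacency_statistic(rep(1, 8)), 8L)
  expect_equal(adjacency_statistic(c(1, 1, 0, 0, 0, 0, 0, 0)), 1L)
  expect_equal(adjacency_statistic(c(1, 0, 0, 0, 1, 0, 0, 0)), 0L)
  expect_error(adjacency_statistic(c(1, 1, 0)), "length 8")
  bits <- all_rings8()
  for (k in 0:8) {
    pmf <- null_adjacency_pmf(k)
    expect_equal(sum(pmf), 1)
    # mean by linearity of expectation over the 8 ring edges
    expect_equal(sum(as.numeric(names(pmf)) * pmf), 8 * k * (k - 1) / (8 * 7))
    # full pmf against direct enumeration of all C(8, k) placements
    sel <- rowSums(bits) == k
    adj <- apply(bits[sel, , drop = FALSE], 1, function(v) sum(v * v[c(2:8, 1)]))
    expect_equal(as.numeric(pmf), as.numeric(table(adj) / sum(sel)))
  }
})

test_that("global tests are deterministic given a seed and detect coupling", {
  ps <- simulate_particle_set(sim_config(1500, binding_model("ising", J = 1),
                                         seed = 18))
  a1 <- arrangement_test(ps, mc_replicates = 2000, seed = 19)
  a2 <- arrangement_test(ps, mc_replicates = 2000, seed = 19)
  expect_identical(a1$p_value, a2$p_value)
  expect_lt(a1$p_value, 0.01)
  d1 <- adjacency_test(ps, mc_replicates = 2000, seed = 19)
  expect_lt(d1$p_value, 0.01)
  # conservation: stratum counts sum to the number of complete k-rings
  for (r in a1$strata) {
    expect_equal(sum(r$table$observed), r$n_effective)
  }
})

test_that("inter-ring pair tallies follow the hypergeometric null", {
  # fully bound particle: all 8 pairs doubly occupied
  ps <- ps_from_occ(occ_of_patterns(list(rep(1, 8)), 2))
  ir <- interring_pair_frequencies(ps)
  row <- ir$by_m[ir$by_m$m == 16, ]
  expect_equal(row$observed, c(0, 0, 8))
  # null double-occupancy probability is monotone in m
  p2 <- vapply(0:16, function(m) interring_pair_null(16, m)$pmf[[3]], numeric(1))
  expect_true(all(diff(p2) >= 0))
  # independent model: stratum proportions within 3.5 SE of the null
  ps <- simulate_particle_set(sim_config(4000, binding_model("independent", p = 0.5),
                                         seed = 25))
  ir <- interring_pair_frequencies(ps, mc_replicates = 2000, seed = 26)
  big <- ir$by_m[ir$by_m$n_particles >= 200, ]
  for (i in seq_len(nrow(big))) {
    p0 <- big$null_prob[i]
    # conservative SE treating the 8 dependent pairs as independent
    se <- sqrt(p0 * (1 - p0) / (8 * big$n_particles[i]))
    expect_lt(abs(big$deviation[i]), 4.5 * se)
  }
  ok_p <- vapply(ir$tests, function(t) t$p_value, numeric(1))
  expect_true(all(is.na(ok_p) | (ok_p >= 0 & ok_p <= 1)))
})

test_that("ring similarity: degenerate particles and null consistency", {
  ps <- ps_from_occ(occ_of_patterns(list(rep(1, 8)), 10))
  rs <- ring_occupancy_similarity(ps)
  expect_equal(rs$statistic, 0)
  expect_equal(rs$absdiff$observed[1], 5)  # all 5 particles at |kA-kB| = 0
  ps <- simulate_particle_set(sim_config(3000, binding_model("independent", p = 0.5),
                                         seed = 27))
  rs <- ring_occupancy_similarity(ps, mc_replicates = 2000, seed = 28)
  expect_gt(rs$p_value, 0.01)
  # strong negative trans-ring coupling inflates the imbalance
  ps2 <- simulate_particle_set(sim_config(3000, binding_model("ising", K = -1.5),
                                          seed = 29))
  rs2 <- ring_occupancy_similarity(ps2, mc_replicates = 2000, seed = 30)
  expect_lt(rs2$p_value, 0.01)
  expect_gt(rs2$statistic, rs2$null_mean)
})

test_that("triplet census counts cyclic windows and validates its spec", {
  recs <- data.frame(rlnImageName = "p1", occRingIndex = rep(0:1, each = 8),
                     occSubunitPosition = rep(0:7, 2),
                     occClassId = rep(c(8L, 1L), 8))
  ps <- assemble_particles(recs)
  tr <- triplet_census(ps, middle_classes = 8, flank_classes = 1:4, n_perm = 0)
  expect_equal(tr$observed, 8L)  # 4 per ring, both rings
  expect_error(triplet_census(ps, integer(0), 1:4), "nonempty")
  expect_error(triplet_census(ps, 8, 99), "outside the class universe")
})

test_that("uniform class usage matches the shuffle null of the triplet census", {
  ps <- simulate_particle_set(sim_config(800, binding_model("independent", p = 0.5),
                                         seed = 35))
  tr <- triplet_census(ps, 8, 1:4, n_perm = 500, seed = 36)
  expect_lt(abs(tr$observed - tr$perm_mean), 3.5 * tr$perm_sd)
  expect_gt(tr$p_value, 0.001)
})

test_that("conformational composition is normalized with bound mass k/8", {
  ps <- simulate_particle_set(sim_config(3000, binding_model("independent", p = 0.5),
                                         seed = 37))
  comp <- conformation_composition(ps)
  cls_cols <- grep("^class_", names(comp), value = TRUE)
  bound_cols <- paste0("class_", 5:8)
  for (i in seq_len(nrow(comp))) {
    if (comp$n_rings[i] == 0) next
    expect_equal(sum(comp[i, cls_cols]), 1)
    expect_equal(sum(comp[i, bound_cols]), comp$k[i] / 8)
  }
  # uniform within-group class choice: each bound class gets ~ k/32
  k4 <- comp[comp$k == 4, ]
  for (cc in bound_cols) {
    expect_lt(abs(k4[[cc]] - 4 / 32), 0.02)
  }
})
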