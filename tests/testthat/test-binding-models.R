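# Generative binding models, noise channel and exact-enumeration oracles.

test_that("model and noise constructors validate parameters", {
  expect_error(binding_model("independent", p = 1.2), "\\[0, 1\\]")
  expect_error(binding_model("mwc", L = -1), "nonnegative")
  expect_error(binding_model("knf", m_total = 17), "0..16")
  expect_error(noise_spec(eps = 0.8, u = 0.3), "eps \\+ u")
})

test_that("degenerate independent models saturate or empty the complex", {
  ps0 <- simulate_particle_set(sim_config(50, binding_model("independent", p = 0), seed = 1))
  expect_true(all(ps0$occ == 0L))
  expect_true(all(ps0$conf %in% 1:4))
  ps1 <- simulate_particle_set(sim_config(50, binding_model("independent", p = 1), seed = 1))
  expect_true(all(ps1$occ == 1L))
  expect_true(all(ps1$conf %in% 5:8))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(80, binding_model("ising", h = 0.3, J = 0.4, K = 0.2),
                    noise = noise_spec(0.05, 0.02), seed = 123)
  t1 <- simulate_particles(cfg)
  t2 <- simulate_particles(cfg)
  expect_identical(t1, t2)
  p1 <- withr::local_tempfile(fileext = ".star")
  p2 <- withr::local_tempfile(fileext = ".star")
  write_star(t1, p1); write_star(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  cfg2 <- sim_config(80, cfg$model, cfg$noise, seed = 124)
  expect_false(identical(simulate_particles(cfg2), t1))
})

test_that("simulate_particle_set equals assembling the emitted table", {
  cfg <- sim_config(60, binding_model("knf", beta = 1, m_total = 6),
                    noise = noise_spec(0.1, 0.05), seed = 77)
  a <- simulate_particle_set(cfg)
  b <- assemble_particles(simulate_particles(cfg), cfg$map)
  expect_identical(a$occ, b$occ)
  expect_identical(a$conf, b$conf)
  expect_equal(a$rings, b$rings)
})

test_that("zero-field Ising binds each site with probability 1/2", {
  cfg <- sim_config(10000, binding_model("ising"), seed = 5)
  ps <- simulate_particle_set(cfg)
  phat <- mean(ps$occ)
  se <- sqrt(0.25 / (10000 * 16))
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("exact_ring_distribution factorizes and normalizes", {
  # J = K = 0 Gibbs equals the independent product law with p = e^h/(1+e^h)
  h <- 0.7
  gibbs <- exact_ring_distribution(binding_model("ising", h = h))
  indep <- exact_ring_distribution(
    binding_model("independent", p = exp(h) / (1 + exp(h))))
  expect_equal(gibbs$pmf, indep$pmf)
  expect_equal(sum(gibbs$pmf), 1)
  joint <- exact_ring_distribution(binding_model("ising", h = 0.2, J = 0.5, K = 0.3))
  expect_equal(joint$level, "particle")
  expect_equal(sum(joint$pmf), 1)
  expect_error(exact_ring_distribution(binding_model("mwc")), "unsupported|supports only")
})

test_that("with J = 0 the exact law conditional on k is the arrangement null", {
  ex <- exact_ring_distribution(binding_model("ising", h = 0.9))$pmf
  bits <- all_rings8()
  kv <- rowSums(bits)
  for (k in c(2, 3, 5)) {
    sel <- kv == k
    canon <- vapply(which(sel), function(i) {
      paste(canonicalize_ring(bits[i, ]), collapse = "")
    }, character(1))
    cond <- tapply(ex[sel], canon, sum)
    cond <- cond / sum(cond)
    null <- null_arrangement_pmf(8, k)
    expect_equal(as.numeric(cond[names(null)]), as.numeric(null))
  }
})

test_that("Ising sampler frequencies converge to the exact Gibbs law", {
  model <- binding_model("ising", h = 0.2, J = 0.5)
  ex <- exact_ring_distribution(model)$pmf
  set.seed(31)
  occ <- sample_occupancy(model, 10000)  # 20000 rings
  codes <- c(as.vector(occ[, 1:8] %*% 2^(0:7)),
             as.vector(occ[, 9:16] %*% 2^(0:7)))
  emp <- tabulate(codes + 1L, 256) / 20000
  tv <- 0.5 * sum(abs(emp - ex))
  expect_lt(tv, 3 * sqrt(256 / 20000))
})

test_that("MWC degenerates correctly and places ligands uniformly given k", {
  # L = 0: always R; huge alpha: fully bound
  set.seed(8)
  occ <- sample_mwc(binding_model("mwc", L = 0, c = 0, alpha = 1e9), 50)
  expect_true(all(occ == 1L))
  # c = 1 collapses T and R: independent binding with p = alpha/(1+alpha)
  model <- binding_model("mwc", L = 4, c = 1, alpha = 1)
  set.seed(9)
  occ <- sample_mwc(model, 8000)
  k <- c(rowSums(occ[, 1:8]), rowSums(occ[, 9:16]))
  pval <- chisq.test(tabulate(k + 1L, 9), p = dbinom(0:8, 8, 0.5))$p.value
  expect_gt(pval, 0.001)
  # conditional on k = 2, all 28 placements equally likely
  set.seed(10)
  occ <- sample_mwc(binding_model("mwc", L = 10, c = 0.2, alpha = 0.4), 20000)
  rings <- rbind(occ[, 1:8], occ[, 9:16])
  k2 <- rings[rowSums(rings) == 2, , drop = FALSE]
  code <- as.vector(k2 %*% 2^(0:7))
  counts <- table(factor(code, levels = sort(unique(
    as.vector(all_rings8()[rowSums(all_rings8()) == 2, ] %*% 2^(0:7))))))
  expect_equal(length(counts), 28L)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("KNF reduces to uniform filling at beta = 0 and clusters at large beta", {
  # beta = 0: uniform m_total-subsets; arrangement classes match the null
  ps <- simulate_particle_set(sim_config(10000, binding_model("knf", beta = 0, m_total = 8),
                                         seed = 21))
  at <- arrangement_test(ps, mc_replicates = 2000, seed = 22)
  expect_gt(at$p_value, 0.001)
  # beta -> +infinity with two ligands: whenever both land in one ring they
  # are adjacent
  set.seed(23)
  occ <- sample_knf(binding_model("knf", beta = 12, m_total = 2), 2000)
  rings <- rbind(occ[, 1:8], occ[, 9:16])
  k2 <- rings[rowSums(rings) == 2, , drop = FALSE]
  expect_gt(nrow(k2), 100)
  adj <- apply(k2, 1, adjacency_statistic)
  expect_true(all(adj == 1L))
  # strongly negative beta enriches the opposite pair above its 4/28 share
  set.seed(24)
  occ <- sample_knf(binding_model("knf", beta = -6, m_total = 4), 6000)
  rings <- rbind(occ[, 1:8], occ[, 9:16])
  k2 <- rings[rowSums(rings) == 2, , drop = FALSE]
  opp <- mean(vapply(seq_len(nrow(k2)), function(i) {
    paste(canonicalize_ring(k2[i, ]), collapse = "") == "00010001"
  }, logical(1)))
  se <- sqrt((4 / 28) * (24 / 28) / nrow(k2))
  expect_gt(opp, 4 / 28 + 3 * se)
})

test_that("the noise channel acts as a per-site flip on the k-marginal", {
  p <- 0.6; eps <- 0.15
  cfg <- sim_config(8000, binding_model("independent", p = p),
                    noise = noise_spec(eps = eps), seed = 33)
  ps <- simulate_particle_set(cfg)
  p_eff <- p * (1 - eps) + (1 - p) * eps
  k <- ps$rings$k[ps$rings$complete]
  pval <- chisq.test(tabulate(k + 1L, 9), p = dbinom(0:8, 8, p_eff))$p.value
  expect_gt(pval, 0.001)
})

test_that("excluded-class noise removes rings at the expected rate", {
  u <- 0.05
  cfg <- sim_config(6000, binding_model("independent", p = 0.5),
                    noise = noise_spec(u = u), seed = 44)
  ps <- simulate_particle_set(cfg)
  frac_complete <- mean(ps$rings$complete)
  expected <- (1 - u)^8
  se <- sqrt(expected * (1 - expected) / nrow(ps$rings))
  expect_lt(abs(frac_complete - expected), 4 * se)
  expect_true(all(ps$conf[!is.na(ps$occ)] %in% 1:8))
})
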