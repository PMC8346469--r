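# Generative models of nucleotide binding on a 2x8-ring complex.
#
# Four equilibrium-snapshot models produce per-subunit bound/unbound states:
#   independent — every site binds with probability p, no coupling;
#   ising       — Gibbs weights exp(h*sum s_i + J*sum_intra s_i s_{i+1} +
#                 K*sum_i s_i^A s_i^B) over all 2^16 configurations
#                 (per-ring 2^8 when K = 0), sampled by exact enumeration;
#   mwc         — each ring concertedly in a T or R state; (state, k) drawn
#                 with weights W(R,k) = C(8,k) alpha^k and
#                 W(T,k) = L C(8,k) (c alpha)^k, then the k ligands placed
#                 uniformly over site subsets, rings independent;
#   knf         — exactly m_total ligands placed sequentially; at each step
#                 an empty site is chosen with probability proportional to
#                 exp(beta * number of bound intra-ring nearest neighbours).
# A classification-noise channel then maps true states to class labels.
#
# Site layout: columns 1..8 are ring 0 positions 0..7, columns 9..16 are
# ring 1 positions 0..7; position i of ring 0 faces position i of ring 1
# (in-register stacking).

#' Specify a generative binding model
#'
#' @param kind One of `"independent"`, `"ising"`, `"mwc"`, `"knf"`.
#' @param p Per-site binding probability (independent).
#' @param h,J,K Ising site field, intra-ring nearest-neighbour coupling and
#'   trans-ring in-register pair coupling, in natural-log units.
#' @param L,c,alpha MWC allosteric constant (T/R at zero ligand), relative
#'   T-state affinity and reduced ligand concentration.
#' @param beta KNF per-bound-neighbour log-preference.
#' @param m_total KNF ligands placed per 16-site particle.
#' @return An object of class `"binding_model"`.
#' @examples
#' binding_model("independent", p = 0.5)
#' binding_model("ising", J = 1)
#' @export
binding_model <- function(kind = c("independent", "ising", "mwc", "knf"),
                          p = 0.5, h = 0, J = 0, K = 0,
                          L = 50, c = 0.05, alpha = 1,
                          beta = 0, m_total = 8) {
  kind <- match.arg(kind)
  if (kind == "independent" && (p < 0 || p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "mwc" && (L < 0 || c < 0 || alpha < 0)) {
    stop("MWC parameters L, c, alpha must be nonnegative", call. = FALSE)
  }
  if (kind == "knf" && (m_total < 0 || m_total > 16)) {
    stop("m_total must lie in 0..16", call. = FALSE)
  }
  structure(list(kind = kind, p = p, h = h, J = J, K = K,
                 L = L, c = c, alpha = alpha,
                 beta = beta, m_total = as.integer(m_total)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  par_str <- switch(x$kind,
    independent = sprintf("p = %g", x$p),
    ising = sprintf("h = %g, J = %g, K = %g", x$h, x$J, x$K),
    mwc = sprintf("L = %g, c = %g, alpha = %g", x$L, x$c, x$alpha),
    knf = sprintf("beta = %g, m_total = %d", x$beta, x$m_total))
  cat(sprintf("<binding_model> %s (%s)\n", x$kind, par_str))
  invisible(x)
}

#' Classification-noise specification
#'
#' Each subunit is, independently: assigned an excluded class with
#' probability `u`; otherwise assigned to the wrong bound/unbound class
#' group with probability `eps`; otherwise classified correctly.  So the
#' marginal misassignment probabilities are exactly `u` and `eps`, and
#' `eps + u <= 1` is required.
#'
#' @param eps Wrong-group probability.
#' @param u Excluded-class probability.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(eps = 0, u = 0) {
  if (eps < 0 || u < 0 || eps + u > 1) {
    stop("need eps >= 0, u >= 0, eps + u <= 1", call. = FALSE)
  }
  structure(list(eps = eps, u = u), class = "noise_spec")
}

#' Simulation configuration
#'
#' A fixed seed makes the emitted table byte-identical across runs: one root
#' seed initializes the generator and every random draw is made in a fixed
#' vectorized order over particle index, so reproducibility does not depend
#' on any iteration order.
#'
#' @param n_particles Number of 16-subunit particles to simulate.
#' @param model A [binding_model()].
#' @param noise A [noise_spec()].
#' @param seed Integer RNG seed.
#' @param map [class_map()] giving the bound/unbound/excluded class labels
#'   that the noise channel and class assignment draw from.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_particles, model = binding_model("independent"),
                       noise = noise_spec(), seed = 1L, map = class_map()) {
  stopifnot(inherits(model, "binding_model"), inherits(noise, "noise_spec"),
            inherits(map, "class_map"), n_particles >= 0)
  structure(list(n_particles = as.integer(n_particles), model = model,
                 noise = noise, seed = as.integer(seed), map = map),
            class = "sim_config")
}

# ---- occupancy samplers (n x 16 integer matrices; use the current RNG) ----

.ring_neighbors <- local({
  left <- c(8L, 1:7, 16L, 9:15)
  right <- c(2:8, 1L, 10:16, 9L)
  list(left = left, right = right)
})

# Per-ring Gibbs pmf over the 256 configurations for given (h, J).
.ising_ring_weights <- function(h, J) {
  tb <- .ring8_tables()
  exp(h * tb$k + J * tb$adj)
}

#' Sample occupancy states from a binding model
#'
#' Draws `n_particles` binding configurations using the current RNG state;
#' wrap in [sim_config()] / [simulate_particles()] for seeded runs.
#'
#' @param model A [binding_model()].
#' @param n_particles Number of particles.
#' @return Integer matrix `n_particles x 16` of 0/1 states (columns 1-8
#'   ring 0, columns 9-16 ring 1, in-register by column offset 8).
#' @export
sample_occupancy <- function(model, n_particles) {
  stopifnot(inherits(model, "binding_model"), n_particles >= 0)
  n <- as.integer(n_particles)
  if (n == 0L) return(matrix(integer(0), 0L, 16L))
  switch(model$kind,
    independent = matrix(stats::rbinom(n * 16L, 1L, model$p), n, 16L),
    ising = .sample_ising(model, n),
    mwc = sample_mwc(model, n),
    knf = sample_knf(model, n))
}

.sample_ising <- function(model, n) {
  tb <- .ring8_tables()
  if (model$K == 0) {
    w <- .ising_ring_weights(model$h, model$J)
    codes <- sample.int(256L, 2L * n, replace = TRUE, prob = w)
    occ <- tb$bits[codes, , drop = FALSE]
    cbind(occ[seq_len(n), , drop = FALSE],
          occ[n + seq_len(n), , drop = FALSE])
  } else {
    wr <- .ising_ring_weights(model$h, model$J)
    pc <- tb$k  # popcount of 0:255
    and_pc <- matrix(pc[bitwAnd(rep(0:255, 256), rep(0:255, each = 256)) + 1L],
                     256L, 256L)
    wjoint <- outer(wr, wr) * exp(model$K * and_pc)
    idx <- sample.int(256L * 256L, n, replace = TRUE, prob = as.vector(wjoint))
    a <- ((idx - 1L) %% 256L) + 1L
    b <- ((idx - 1L) %/% 256L) + 1L
    cbind(tb$bits[a, , drop = FALSE], tb$bits[b, , drop = FALSE])
  }
}

#' Sample particle states from the concerted (MWC) model
#'
#' @param model A `binding_model` of kind `"mwc"`.
#' @param n_particles Number of particles.
#' @return Integer matrix `n_particles x 16`.
#' @export
sample_mwc <- function(model, n_particles) {
  stopifnot(model$kind == "mwc")
  n <- as.integer(n_particles)
  kk <- 0:8
  wR <- choose(8, kk) * model$alpha^kk
  wT <- model$L * choose(8, kk) * (model$c * model$alpha)^kk
  w <- c(wR, wT)  # 18 (state, k) cells; index 1..9 -> R with k-1, 10..18 -> T
  pick <- sample.int(18L, 2L * n, replace = TRUE, prob = w)
  k_ring <- kk[((pick - 1L) %% 9L) + 1L]
  occ <- matrix(0L, 2L * n, 8L)
  for (i in seq_len(2L * n)) {
    if (k_ring[i] > 0L) occ[i, sample.int(8L, k_ring[i])] <- 1L
  }
  cbind(occ[seq_len(n), , drop = FALSE], occ[n + seq_len(n), , drop = FALSE])
}

#' Sample particle states from the sequential-fill (KNF) model
#'
#' Places exactly `m_total` ligands per particle, one at a time; each step
#' picks an empty site with probability proportional to
#' `exp(beta * bound intra-ring nearest neighbours)`.
#'
#' @inheritParams sample_mwc
#' @export
sample_knf <- function(model, n_particles) {
  stopifnot(model$kind == "knf")
  n <- as.integer(n_particles)
  occ <- matrix(0L, n, 16L)
  if (n == 0L || model$m_total == 0L) return(occ)
  nb <- .ring_neighbors
  for (step in seq_len(model$m_total)) {
    nbr <- occ[, nb$left, drop = FALSE] + occ[, nb$right, drop = FALSE]
    w <- exp(model$beta * nbr) * (occ == 0L)
    cw <- w
    for (j in 2:16) cw[, j] <- cw[, j - 1L] + w[, j]
    u <- stats::runif(n) * cw[, 16L]
    pick <- rowSums(cw < u) + 1L
    occ[cbind(seq_len(n), pick)] <- 1L
  }
  occ
}

# ---- exact distribution oracle ----

#' Exact configuration distribution of an enumerable binding model
#'
#' Brute-force oracle for the independent and Ising models.  With no
#' trans-ring coupling (`K = 0`) the two rings are independent and the
#' per-ring distribution over the 2^8 configurations is returned; otherwise
#' the full 2^16 particle distribution is enumerated as a 256 x 256 matrix
#' (rows ring 0, columns ring 1, both indexed by pattern code + 1).
#'
#' @param model A `binding_model` of kind `"independent"` or `"ising"`.
#' @return List with `level` (`"ring"` or `"particle"`) and `pmf` (length-256
#'   vector, or 256 x 256 matrix), normalized.  Pattern code of a 0/1 vector
#'   `v` is `sum(v * 2^(0:7))`.
#' @export
exact_ring_distribution <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  tb <- .ring8_tables()
  if (model$kind == "independent") {
    w <- model$p^tb$k * (1 - model$p)^(8 - tb$k)
    return(list(level = "ring", pmf = w / sum(w)))
  }
  if (model$kind != "ising") {
    stop("exact enumeration supports only independent and ising models",
         call. = FALSE)
  }
  wr <- .ising_ring_weights(model$h, model$J)
  if (model$K == 0) {
    return(list(level = "ring", pmf = wr / sum(wr)))
  }
  pc <- tb$k
  and_pc <- matrix(pc[bitwAnd(rep(0:255, 256), rep(0:255, each = 256)) + 1L],
                   256L, 256L)
  wjoint <- outer(wr, wr) * exp(model$K * and_pc)
  list(level = "particle", pmf = wjoint / sum(wjoint))
}

# ---- table emission ----

# Draw conformational class labels (n x 16) for true occupancy states,
# applying the noise channel, in a fixed vectorized order.
.assign_classes <- function(occ, noise, map) {
  n <- nrow(occ)
  u01 <- matrix(stats::runif(n * 16L), n, 16L)
  state <- occ
  wrong <- u01 >= noise$u & u01 < noise$u + noise$eps
  state[wrong] <- 1L - state[wrong]
  excl <- u01 < noise$u
  cls <- matrix(NA_integer_, n, 16L)
  pickb <- matrix(sample(map$bound, n * 16L, replace = TRUE), n, 16L)
  picku <- matrix(sample(map$unbound, n * 16L, replace = TRUE), n, 16L)
  cls[state == 1L] <- pickb[state == 1L]
  cls[state == 0L] <- picku[state == 0L]
  if (length(map$excluded) && any(excl)) {
    picke <- matrix(sample(map$excluded, n * 16L, replace = TRUE), n, 16L)
    cls[excl] <- picke[excl]
  }
  cls
}

.simulate_classes <- function(config) {
  set.seed(config$seed)
  occ <- sample_occupancy(config$model, config$n_particles)
  cls <- .assign_classes(occ, config$noise, config$map)
  pid <- sprintf("particle_%06d", seq_len(config$n_particles))
  list(pid = pid, occ = occ, cls = cls)
}

#' Simulate a classified-subunit table
#'
#' Runs the binding model, applies the classification-noise channel, and
#' emits a subunit-level record table in the same dialect the analysis
#' pipeline ingests: 16 rows per particle with columns `rlnImageName`,
#' `occRingIndex`, `occSubunitPosition`, `occClassId`.  Bound subunits get a
#' class drawn uniformly from the map's bound set, unbound from the unbound
#' set.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Subunit-record data.frame with `16 * n_particles` rows.
#' @export
simulate_particles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- .simulate_classes(config)
  n <- config$n_particles
  data.frame(
    rlnImageName = rep(sim$pid, each = 16L),
    occRingIndex = rep(rep(0:1, each = 8L), times = n),
    occSubunitPosition = rep(rep(0:7, times = 2L), times = n),
    occClassId = as.integer(t(sim$cls)),
    stringsAsFactors = FALSE
  )
}

#' Simulate directly to an assembled particle set
#'
#' Identical draws to [simulate_particles()] under the same config (the two
#' share one sampler), but skips the table round-trip:
#' `simulate_particle_set(cfg)` equals
#' `assemble_particles(simulate_particles(cfg), cfg$map)`.
#'
#' @inheritParams simulate_particles
#' @return A `particle_set`.
#' @export
simulate_particle_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- .simulate_classes(config)
  n <- config$n_particles
  map <- config$map
  odd <- seq_len(n) * 2L - 1L
  conf <- matrix(NA_integer_, 2L * n, 8L)
  conf[odd, ] <- sim$cls[, 1:8, drop = FALSE]
  conf[odd + 1L, ] <- sim$cls[, 9:16, drop = FALSE]
  occ <- matrix(as.integer(conf %in% map$bound), 2L * n, 8L)
  is_excl <- matrix(conf %in% map$excluded, 2L * n, 8L)
  occ[is_excl] <- NA_integer_
  status <- ifelse(rowSums(is_excl) > 0L, "has_excluded", "complete")
  complete <- status == "complete"
  k <- ifelse(complete, rowSums(occ), NA_integer_)
  rings <- data.frame(
    particle_id = rep(sim$pid, each = 2L),
    ring_index = rep(0:1, times = n),
    status = status, complete = complete, k = as.integer(k),
    stringsAsFactors = FALSE
  )
  both <- complete[odd] & complete[odd + 1L]
  rings$paired <- rep(both, each = 2L)
  structure(list(rings = rings, occ = occ, conf = conf, class_map = map),
            class = "particle_set")
}
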