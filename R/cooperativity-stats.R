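# Occupancy and cooperativity statistics on assembled particle sets.
#
# All arrangement tests condition on the per-ring ligand count k (or the
# per-particle total m for inter-ring tests), so they are sensitive to the
# *placement* of nucleotides, not to the occupancy distribution itself.
# That conditioning is the logical core: a concerted (MWC-type) mechanism
# changes how many sites are bound but places them uniformly, so it is
# invisible to these tests, whereas nearest-neighbour (KNF/Ising-type)
# coupling distorts the within-k arrangement frequencies.
#
# Goodness-of-fit defaults to a Monte Carlo exact multinomial test (Pearson
# statistic, null resampled from the multinomial with a fixed seed) because
# per-class expected counts can be small at extreme k; asymptotic Pearson
# and G variants remain selectable.

# Cached per-k arrangement-class lookup for the 8-ring: canonical strings in
# sorted order, null probabilities, and a 256-slot map pattern-code -> class.
.k_class_info <- function(k) {
  key <- paste0("kinfo", k)
  if (!is.null(.ringocc_cache[[key]])) return(.ringocc_cache[[key]])
  tb <- .ring8_tables()
  cls <- enumerate_classes(8, k)
  canon_codes <- vapply(cls$canonical,
                        function(s) sum(ring_from_string(s) * 2L^(0:7)), numeric(1))
  code_to_class <- rep(NA_integer_, 256L)
  sel <- which(tb$k == k)
  code_to_class[sel] <- match(tb$canon[sel], canon_codes)
  info <- list(classes = cls, code_to_class = code_to_class)
  .ringocc_cache[[key]] <- info
  info
}

.mc_pvalue_ge <- function(obs, sims) {
  (1 + sum(sims >= obs - 1e-9)) / (length(sims) + 1)
}

.pearson_stat <- function(obs, expected) {
  ok <- expected > 0
  sum((obs[ok] - expected[ok])^2 / expected[ok])
}

#' Nucleotide-occupancy histogram
#'
#' Counts complete rings by per-ring occupancy `k = 0..8`, or paired
#' particles by total occupancy `m = 0..16`.  The mean fractional
#' saturation (bound sites / total sites) is attached as attribute
#' `"saturation"`.
#'
#' @param ps A `particle_set`.
#' @param level `"ring"` or `"particle"` (particle level uses paired
#'   particles only).
#' @return Data.frame with columns `k` (or `m`), `count`, `proportion`.
#' @export
occupancy_histogram <- function(ps, level = c("ring", "particle")) {
  level <- match.arg(level)
  stopifnot(inherits(ps, "particle_set"))
  if (level == "ring") {
    k <- ps$rings$k[ps$rings$complete]
    if (!length(k)) warning("no complete rings; empty histogram")
    counts <- tabulate(k + 1L, nbins = 9L)
    out <- data.frame(k = 0:8, count = counts,
                      proportion = if (sum(counts)) counts / sum(counts) else 0)
    attr(out, "saturation") <- if (length(k)) mean(k) / 8 else NA_real_
  } else {
    po <- .paired_occ(ps)
    m <- rowSums(po$ring0) + rowSums(po$ring1)
    if (!length(m)) warning("no paired particles; empty histogram")
    counts <- tabulate(m + 1L, nbins = 17L)
    out <- data.frame(m = 0:16, count = counts,
                      proportion = if (sum(counts)) counts / sum(counts) else 0)
    attr(out, "saturation") <- if (length(m)) mean(m) / 16 else NA_real_
  }
  out
}

.new_freq_report <- function(stratum, table, statistic, kind, p_value,
                             n_effective, mc_replicates = NA_integer_,
                             seed = NA_integer_) {
  structure(list(stratum = stratum, table = table, statistic = statistic,
                 statistic_kind = kind, p_value = p_value,
                 n_effective = n_effective, mc_replicates = mc_replicates,
                 seed = seed),
            class = "freq_report")
}

#' @export
print.freq_report <- function(x, ...) {
  cat(sprintf("<freq_report> stratum %s: n = %d, %s statistic = %s, p = %s\n",
              x$stratum, x$n_effective, x$statistic_kind,
              format(x$statistic, digits = 4),
              if (is.na(x$p_value)) "NA (descriptive)" else format(x$p_value, digits = 4)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Observed vs random-binding arrangement frequencies at occupancy k
#'
#' Canonicalizes every complete ring with `k` bound subunits, tallies the
#' arrangement classes and compares the class frequencies with the
#' random-binding null (`orbit_size / C(8, k)`) by the chosen
#' goodness-of-fit method.
#'
#' @param ps A `particle_set`.
#' @param k Ring occupancy stratum, 0..8.
#' @param method `"mc"` (Monte Carlo exact multinomial, default),
#'   `"chisq"` (asymptotic Pearson) or `"g"` (likelihood-ratio G with
#'   asymptotic reference).
#' @param mc_replicates Monte Carlo resamples (default 10000).
#' @param seed Optional integer seed for the Monte Carlo draw.
#' @param min_stratum Below this many rings the report is descriptive
#'   (statistic computed, `p_value = NA`); default 20.
#' @return A `freq_report`.
#' @export
arrangement_frequencies <- function(ps, k, method = c("mc", "chisq", "g"),
                                    mc_replicates = 10000, seed = NULL,
                                    min_stratum = 20) {
  method <- match.arg(method)
  stopifnot(inherits(ps, "particle_set"), k >= 0, k <= 8)
  occ <- .complete_occ(ps)
  occ <- occ[rowSums(occ) == k, , drop = FALSE]
  info <- .k_class_info(k)
  cls_idx <- info$code_to_class[.occ_codes(occ) + 1L]
  obs <- tabulate(cls_idx, nbins = nrow(info$classes))
  n <- nrow(occ)
  p0 <- info$classes$null_prob
  expected <- n * p0
  tab <- data.frame(canonical = info$classes$canonical,
                    observed = obs,
                    proportion = if (n) obs / n else 0,
                    null_prob = p0,
                    expected = expected,
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    return(.new_freq_report(paste0("k=", k), tab, NA_real_, method, NA_real_, 0L))
  }
  stat <- if (method == "g") {
    pos <- obs > 0
    2 * sum(obs[pos] * log(obs[pos] / expected[pos]))
  } else .pearson_stat(obs, expected)
  df <- nrow(tab) - 1L
  if (n < min_stratum || df == 0L) {
    return(.new_freq_report(paste0("k=", k), tab, stat, method, NA_real_, n))
  }
  if (method == "mc") {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::rmultinom(mc_replicates, n, p0)
    simstat <- colSums((sims - expected)^2 / expected)
    p <- .mc_pvalue_ge(stat, simstat)
    .new_freq_report(paste0("k=", k), tab, stat, "mc_pearson", p, n,
                     as.integer(mc_replicates), seed %||% NA_integer_)
  } else {
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    .new_freq_report(paste0("k=", k), tab, stat, method, p, n)
  }
}

#' Global arrangement goodness-of-fit test across occupancy strata
#'
#' Sums the per-stratum Pearson statistics over all occupancy levels with at
#' least `min_stratum` complete rings (and more than one arrangement class,
#' i.e. `k = 1..7`) and computes a single Monte Carlo p-value by jointly
#' resampling every stratum's class counts from its random-binding
#' multinomial null, conditional on the observed stratum sizes.
#'
#' @inheritParams arrangement_frequencies
#' @param ks Candidate strata (default 1:7; k = 0 and 8 have a single class).
#' @return List of class `"coop_test"`: `statistic`, `p_value`, `strata`
#'   (per-stratum `freq_report`s), `n_strata`, `mc_replicates`, `seed`.
#' @export
arrangement_test <- function(ps, ks = 1:7, mc_replicates = 10000, seed = NULL,
                             min_stratum = 20) {
  stopifnot(inherits(ps, "particle_set"))
  if (!is.null(seed)) set.seed(seed)
  occ <- .complete_occ(ps)
  kvec <- rowSums(occ)
  codes <- .occ_codes(occ)
  total <- 0
  simtotal <- rep(0, mc_replicates)
  reports <- list()
  used <- integer(0)
  for (k in ks) {
    info <- .k_class_info(k)
    if (nrow(info$classes) < 2L) next
    sel <- kvec == k
    n <- sum(sel)
    if (n < min_stratum) next
    obs <- tabulate(info$code_to_class[codes[sel] + 1L],
                    nbins = nrow(info$classes))
    p0 <- info$classes$null_prob
    expected <- n * p0
    stat <- .pearson_stat(obs, expected)
    sims <- stats::rmultinom(mc_replicates, n, p0)
    simstat <- colSums((sims - expected)^2 / expected)
    total <- total + stat
    simtotal <- simtotal + simstat
    used <- c(used, k)
    tab <- data.frame(canonical = info$classes$canonical, observed = obs,
                      proportion = obs / n, null_prob = p0, expected = expected,
                      stringsAsFactors = FALSE)
    reports[[paste0("k=", k)]] <-
      .new_freq_report(paste0("k=", k), tab, stat, "mc_pearson",
                       .mc_pvalue_ge(stat, simstat), n,
                       as.integer(mc_replicates), seed %||% NA_integer_)
  }
  p <- if (length(used)) .mc_pvalue_ge(total, simtotal) else NA_real_
  structure(list(test = "arrangement", statistic = total, p_value = p,
                 strata = reports, n_strata = length(used), used_k = used,
                 mc_replicates = as.integer(mc_replicates),
                 seed = seed %||% NA_integer_),
            class = "coop_test")
}

#' @export
print.coop_test <- function(x, ...) {
  cat(sprintf("<coop_test> %s: %d strata, statistic = %s, p = %s\n",
              x$test, x$n_strata, format(x$statistic, digits = 4),
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4)))
  invisible(x)
}

#' Count of adjacent bound-bound pairs on a ring
#'
#' The one-dimensional cooperativity summary `sum_i s_i * s_{i+1 mod 8}`.
#'
#' @param occ Complete 0/1 occupancy vector of length 8.
#' @return Integer in 0..8.
#' @export
adjacency_statistic <- function(occ) {
  occ <- .validate_ring(occ, n = 8L)
  sum(occ * occ[c(2:8, 1L)])
}

#' Exact null pmf of the adjacency statistic at occupancy k
#'
#' Distribution of [adjacency_statistic()] over all `C(8, k)` equally likely
#' placements of `k` ligands on the 8-ring, by exhaustive enumeration.  Its
#' mean is `8 * k * (k - 1) / (8 * 7)` by linearity of expectation over the
#' 8 ring edges.
#'
#' @param k Ligand count, 0..8.
#' @return Named numeric pmf over the statistic's support.
#' @export
null_adjacency_pmf <- function(k) {
  stopifnot(k >= 0, k <= 8)
  tb <- .ring8_tables()
  adj <- tb$adj[tb$k == k]
  tab <- table(adj) / length(adj)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Global adjacency test across occupancy strata
#'
#' For each occupancy stratum k the total adjacency count over its rings is
#' standardized by the exact null mean and variance; the global statistic is
#' the sum of squared standardized totals, with a Monte Carlo reference
#' obtained by resampling per-ring adjacency values from the exact null pmf
#' (as multinomial draws over the statistic's support), conditional on the
#' observed stratum sizes.  Two-sided by construction: both clustering
#' (Ising J > 0, KNF beta > 0) and dispersion (beta < 0) inflate it.
#'
#' @inheritParams arrangement_test
#' @param ks Candidate strata (default 2:7; below k = 2 the statistic is
#'   degenerate at 0, at k = 8 it is degenerate at 8).
#' @return A `"coop_test"` list; `strata` holds per-stratum summaries
#'   (observed total, null mean/variance, z).
#' @export
adjacency_test <- function(ps, ks = 2:7, mc_replicates = 10000, seed = NULL,
                           min_stratum = 20) {
  stopifnot(inherits(ps, "particle_set"))
  if (!is.null(seed)) set.seed(seed)
  tb <- .ring8_tables()
  occ <- .complete_occ(ps)
  kvec <- rowSums(occ)
  adjvec <- tb$adj[.occ_codes(occ) + 1L]
  total <- 0
  simtotal <- rep(0, mc_replicates)
  strata <- list()
  used <- integer(0)
  for (k in ks) {
    sel <- kvec == k
    n <- sum(sel)
    if (n < min_stratum) next
    pmf <- null_adjacency_pmf(k)
    support <- as.numeric(names(pmf))
    if (length(support) < 2L) next
    mu <- sum(support * pmf)
    v <- sum((support - mu)^2 * pmf)
    Tobs <- sum(adjvec[sel])
    z <- (Tobs - n * mu) / sqrt(n * v)
    counts <- stats::rmultinom(mc_replicates, n, pmf)
    Tsim <- colSums(counts * support)
    zsim <- (Tsim - n * mu) / sqrt(n * v)
    total <- total + z^2
    simtotal <- simtotal + zsim^2
    used <- c(used, k)
    strata[[paste0("k=", k)]] <- list(k = k, n = n, observed_total = Tobs,
                                      null_mean = n * mu, null_var = n * v,
                                      z = z)
  }
  p <- if (length(used)) .mc_pvalue_ge(total, simtotal) else NA_real_
  structure(list(test = "adjacency", statistic = total, p_value = p,
                 strata = strata, n_strata = length(used), used_k = used,
                 mc_replicates = as.integer(mc_replicates),
                 seed = seed %||% NA_integer_),
            class = "coop_test")
}

#' Inter-ring pair occupancy vs the hypergeometric null
#'
#' For every paired particle, tallies the number `j = 0, 1, 2` of bound
#' subunits over its 8 in-register trans-ring pairs, stratified by the
#' particle's total occupancy `m`; compares each stratum's pooled `j`
#' frequencies with the random-placement null [interring_pair_null()].
#' Pairs within a particle are dependent, so significance comes from a
#' particle-level Monte Carlo: the number of doubly occupied pairs per
#' particle is resampled from its exact null pmf.
#'
#' @inheritParams arrangement_frequencies
#' @return List of class `"interring_report"`: `by_m` data.frame (per m and
#'   j: observed count/proportion, null probability, deviation), `tests`
#'   (per-m `freq_report`s), `n_particles`, and a saturation summary.
#' @export
interring_pair_frequencies <- function(ps, mc_replicates = 10000, seed = NULL,
                                       min_stratum = 20) {
  stopifnot(inherits(ps, "particle_set"))
  if (!is.null(seed)) set.seed(seed)
  po <- .paired_occ(ps)
  n_pairs_tot <- nrow(po$ring0)
  if (n_pairs_tot == 0L) {
    warning("no paired particles; empty inter-ring report")
    return(structure(list(by_m = data.frame(), tests = list(),
                          n_particles = 0L, saturation = NA_real_),
                     class = "interring_report"))
  }
  jmat <- po$ring0 + po$ring1            # per particle, per position: 0/1/2
  m <- rowSums(jmat)
  rows <- list()
  tests <- list()
  for (mm in sort(unique(m))) {
    sel <- m == mm
    nm <- sum(sel)
    obs <- vapply(0:2, function(j) sum(jmat[sel, , drop = FALSE] == j), numeric(1))
    null <- interring_pair_null(16, mm)$pmf
    expected <- 8 * nm * null
    rows[[length(rows) + 1L]] <- data.frame(
      m = mm, j = 0:2, n_particles = nm, observed = obs,
      proportion = obs / (8 * nm), null_prob = as.numeric(null),
      deviation = obs / (8 * nm) - as.numeric(null))
    stat <- .pearson_stat(obs, expected)
    tab <- data.frame(j = 0:2, observed = obs, proportion = obs / (8 * nm),
                      null_prob = as.numeric(null), expected = expected)
    if (nm < min_stratum || mm %in% c(0L, 16L)) {
      tests[[paste0("m=", mm)]] <-
        .new_freq_report(paste0("m=", mm), tab, stat, "mc_pearson", NA_real_, nm)
      next
    }
    dpmf <- .pair_double_pmf(mm)
    dvals <- as.numeric(names(dpmf))
    counts <- stats::rmultinom(mc_replicates, nm, dpmf)
    N2 <- colSums(counts * dvals)
    N1 <- mm * nm - 2 * N2
    N0 <- 8 * nm - N1 - N2
    simmat <- rbind(N0, N1, N2)
    ok <- expected > 0
    simstat <- colSums((simmat[ok, , drop = FALSE] - expected[ok])^2 /
                         expected[ok])
    tests[[paste0("m=", mm)]] <-
      .new_freq_report(paste0("m=", mm), tab, stat, "mc_pearson",
                       .mc_pvalue_ge(stat, simstat), nm,
                       as.integer(mc_replicates), seed %||% NA_integer_)
  }
  structure(list(by_m = do.call(rbind, rows), tests = tests,
                 n_particles = n_pairs_tot, saturation = mean(m) / 16),
            class = "interring_report")
}

#' @export
print.interring_report <- function(x, ...) {
  cat(sprintf("<interring_report> %d paired particles, saturation %.3f, %d m-strata tested\n",
              x$n_particles, x$saturation,
              sum(!vapply(x$tests, function(t) is.na(t$p_value), logical(1)))))
  invisible(x)
}

#' Similarity of the two rings' occupancies vs the random-split null
#'
#' Tallies the joint per-ring occupancies `(kA, kB)` of paired particles and
#' compares the total inter-ring imbalance `sum |kA - kB|` with the
#' hypergeometric null [ring_split_null()] conditional on each particle's
#' total `m`, by two-sided Monte Carlo resampling of ring splits.
#'
#' @inheritParams arrangement_frequencies
#' @return List of class `"ring_similarity"`: `joint` (9 x 9 count matrix),
#'   `absdiff` (observed and null-expected distribution of `|kA - kB|`),
#'   `statistic` (observed total imbalance), `null_mean`, `p_value`.
#' @export
ring_occupancy_similarity <- function(ps, mc_replicates = 10000, seed = NULL) {
  stopifnot(inherits(ps, "particle_set"))
  if (!is.null(seed)) set.seed(seed)
  po <- .paired_occ(ps)
  kA <- rowSums(po$ring0)
  kB <- rowSums(po$ring1)
  if (!length(kA)) {
    warning("no paired particles; empty similarity report")
    return(structure(list(joint = matrix(0, 9, 9), absdiff = data.frame(),
                          statistic = NA_real_, null_mean = NA_real_,
                          p_value = NA_real_, n_particles = 0L),
                     class = "ring_similarity"))
  }
  joint <- table(factor(kA, levels = 0:8), factor(kB, levels = 0:8))
  Sobs <- sum(abs(kA - kB))
  m <- kA + kB
  Ssim <- rep(0, mc_replicates)
  exp_absdiff <- rep(0, 17)  # |kA-kB| in 0..16 (only 0..8 feasible)
  for (mm in sort(unique(m))) {
    nm <- sum(m == mm)
    pmf <- ring_split_null(16, mm)
    support <- 0:8
    absd <- abs(2 * support - mm)
    counts <- stats::rmultinom(mc_replicates, nm, pmf)
    Ssim <- Ssim + colSums(counts * absd)
    exp_absdiff <- exp_absdiff + nm * vapply(0:16, function(d) sum(pmf[absd == d]),
                                             numeric(1))
  }
  obs_absdiff <- tabulate(abs(kA - kB) + 1L, nbins = 17L)
  p_hi <- .mc_pvalue_ge(Sobs, Ssim)
  p_lo <- .mc_pvalue_ge(-Sobs, -Ssim)
  structure(list(joint = unclass(joint),
                 absdiff = data.frame(d = 0:16, observed = obs_absdiff,
                                      expected = exp_absdiff),
                 statistic = Sobs,
                 null_mean = mean(Ssim),
                 p_value = min(1, 2 * min(p_hi, p_lo)),
                 n_particles = length(kA),
                 mc_replicates = as.integer(mc_replicates),
                 seed = seed %||% NA_integer_),
            class = "ring_similarity")
}

#' @export
print.ring_similarity <- function(x, ...) {
  cat(sprintf("<ring_similarity> %d paired particles, sum|kA-kB| = %s (null mean %s), p = %s\n",
              x$n_particles, format(x$statistic),
              format(x$null_mean, digits = 4),
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4)))
  invisible(x)
}

#' Census of conformational triplets around the ring
#'
#' Counts cyclic position windows `(i - 1, i, i + 1)` in which the middle
#' subunit's class is in `middle_classes` and both flanking subunits'
#' classes are in `flank_classes`, over all complete rings.  The expected
#' count under within-ring label shuffling is estimated by permutation
#' (labels permuted independently within each ring, fixed seed).
#'
#' @param ps A `particle_set`.
#' @param middle_classes,flank_classes Nonempty class-id sets from the class
#'   universe.
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Optional seed for the permutation draw.
#' @return List of class `"triplet_report"`: `observed` total count,
#'   `per_ring` mean, `perm_mean`, `perm_sd`, two-sided `p_value`,
#'   `n_rings`.
#' @export
triplet_census <- function(ps, middle_classes, flank_classes, n_perm = 1000,
                           seed = NULL) {
  stopifnot(inherits(ps, "particle_set"))
  middle_classes <- as.integer(middle_classes)
  flank_classes <- as.integer(flank_classes)
  if (!length(middle_classes) || !length(flank_classes)) {
    stop("middle_classes and flank_classes must be nonempty", call. = FALSE)
  }
  bad <- setdiff(c(middle_classes, flank_classes), ps$class_map$universe)
  if (length(bad)) {
    stop("class id(s) outside the class universe: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  conf <- ps$conf[ps$rings$complete, , drop = FALSE]
  n <- nrow(conf)
  count_triplets <- function(cm) {
    mid <- matrix(cm %in% middle_classes, nrow(cm), 8L)
    fl <- matrix(cm %in% flank_classes, nrow(cm), 8L)
    left <- fl[, c(8L, 1:7), drop = FALSE]
    right <- fl[, c(2:8, 1L), drop = FALSE]
    sum(left & mid & right)
  }
  obs <- count_triplets(conf)
  if (n == 0L || n_perm == 0L) {
    return(structure(list(observed = obs, per_ring = NA_real_,
                          perm_mean = NA_real_, perm_sd = NA_real_,
                          p_value = NA_real_, n_rings = n),
                     class = "triplet_report"))
  }
  if (!is.null(seed)) set.seed(seed)
  v <- as.vector(t(conf))            # ring blocks contiguous
  blk <- rep(seq_len(n), each = 8L)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    o <- order(blk, stats::runif(8L * n))
    pm <- matrix(v[o], n, 8L, byrow = TRUE)
    perm[b] <- count_triplets(pm)
  }
  p_hi <- .mc_pvalue_ge(obs, perm)
  p_lo <- .mc_pvalue_ge(-obs, -perm)
  structure(list(observed = obs, per_ring = obs / n,
                 perm_mean = mean(perm), perm_sd = stats::sd(perm),
                 p_value = min(1, 2 * min(p_hi, p_lo)), n_rings = n,
                 n_perm = as.integer(n_perm), seed = seed %||% NA_integer_),
            class = "triplet_report")
}

#' @export
print.triplet_report <- function(x, ...) {
  cat(sprintf("<triplet_report> %d triplets over %d rings (%.3f/ring); shuffle mean %.1f, p = %s\n",
              x$observed, x$n_rings, x$per_ring, x$perm_mean,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4)))
  invisible(x)
}

#' Conformational-class composition by ring occupancy
#'
#' For each occupancy level k, the fraction of each conformational class
#' among all subunits of complete rings with that k.  Rows sum to 1; the
#' bound-class fractions sum to `k/8` and the unbound-class fractions to
#' `(8 - k)/8` by construction of the class map.
#'
#' @param ps A `particle_set`.
#' @return Data.frame: `k`, `n_rings`, then one `class_<id>` column per
#'   non-excluded class.
#' @export
conformation_composition <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  ok <- ps$rings$complete
  conf <- ps$conf[ok, , drop = FALSE]
  kvec <- ps$rings$k[ok]
  classes <- sort(c(ps$class_map$bound, ps$class_map$unbound))
  out <- lapply(0:8, function(k) {
    cm <- conf[kvec == k, , drop = FALSE]
    n <- nrow(cm)
    frac <- if (n) vapply(classes, function(cl) mean(cm == cl), numeric(1))
            else rep(NA_real_, length(classes))
    c(k = k, n_rings = n, stats::setNames(frac, paste0("class_", classes)))
  })
  as.data.frame(do.call(rbind, out))
}
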