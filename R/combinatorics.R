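# Binary-necklace combinatorics for ligand arrangements on an n-membered ring.
#
# An arrangement is a length-n binary occupancy vector (1 = nucleotide-bound).
# Two arrangements are equivalent when one is a cyclic rotation of the other;
# the equivalence classes are binary necklaces.  Under random binding of k
# ligands every one of the C(n, k) raw placements is equally likely, so a
# class's null probability is its orbit size divided by C(n, k).

.validate_ring <- function(occ, n = NULL) {
  if (!is.numeric(occ) && !is.logical(occ)) {
    stop("ring occupancy must be a numeric or logical vector", call. = FALSE)
  }
  occ <- as.integer(occ)
  if (!is.null(n) && length(occ) != n) {
    stop(sprintf("ring occupancy must have length %d, got %d", n, length(occ)),
         call. = FALSE)
  }
  if (length(occ) < 1L || anyNA(occ) || !all(occ %in% c(0L, 1L))) {
    stop("ring occupancy must contain only 0 and 1", call. = FALSE)
  }
  occ
}

.rotations <- function(occ) {
  n <- length(occ)
  idx <- outer(seq_len(n) - 1L, seq_len(n) - 1L, function(r, i) (i + r) %% n) + 1L
  matrix(occ[idx], nrow = n)  # row r = rotation by r-1
}

#' Canonical (rotation-minimal) form of a ring occupancy vector
#'
#' Returns the lexicographically smallest cyclic rotation of `occ`, reading
#' positions in increasing index order.  The result is the class
#' representative used throughout the package: it is idempotent and constant
#' on rotation orbits, so two occupancy vectors describe the same arrangement
#' class if and only if their canonical forms are identical.
#'
#' @param occ Integer (0/1) occupancy vector; any ring size `>= 1`.
#' @param symmetry `"cyclic"` (default) minimizes over rotations only;
#'   `"dihedral"` also minimizes over the reflected vector's rotations
#'   (bracelet equivalence), for sensitivity analyses.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' canonicalize_ring(c(0, 0, 0, 1, 1, 0, 0, 0))
#' @export
canonicalize_ring <- function(occ, symmetry = c("cyclic", "dihedral")) {
  symmetry <- match.arg(symmetry)
  occ <- .validate_ring(occ)
  rots <- .rotations(occ)
  if (symmetry == "dihedral") rots <- rbind(rots, .rotations(rev(occ)))
  keys <- apply(rots, 1L, paste, collapse = "")
  as.integer(rots[which.min(match(keys, sort(keys))), ])
}

.ring_string <- function(occ) paste(occ, collapse = "")

#' Parse an arrangement string such as "11000000" back to a 0/1 vector
#' @param s Character scalar of 0s and 1s.
#' @return Integer vector.
#' @export
ring_from_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .validate_ring(as.integer(strsplit(s, "")[[1L]]))
}

# Cached per-pattern tables for the default n = 8 ring: canonical pattern
# code, ligand count and adjacent bound-bound pair count for every one of the
# 256 patterns.  Pattern code = sum(occ * 2^(0:7)).
.ringocc_cache <- new.env(parent = emptyenv())

.ring8_tables <- function() {
  if (!is.null(.ringocc_cache$ring8)) return(.ringocc_cache$ring8)
  codes <- 0:255
  bits <- t(vapply(codes, function(x) as.integer(intToBits(x)[1:8]), integer(8)))
  k <- rowSums(bits)
  canon <- integer(256)
  adj <- integer(256)
  for (i in seq_len(256)) {
    v <- bits[i, ]
    canon[i] <- sum(canonicalize_ring(v) * 2L^(0:7))
    adj[i] <- sum(v * v[c(2:8, 1)])
  }
  .ringocc_cache$ring8 <- list(bits = bits, k = k, canon = canon, adj = adj)
  .ringocc_cache$ring8
}

.occ_codes <- function(occ_mat) as.vector(occ_mat %*% 2L^(0:7))

#' Number of rotationally distinct arrangements of k ligands on an n-ring
#'
#' Closed-form binary-necklace count by Burnside's lemma over the cyclic
#' group: `(1/n) * sum over d | gcd(n, k) of phi(d) * C(n/d, k/d)`.
#'
#' @param n Ring size.
#' @param k Ligand count, `0 <= k <= n`.
#' @return Integer class count.
#' @examples
#' count_classes(8, 2)  # 4
#' @export
count_classes <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 1)
  if (k < 0 || k > n) stop("k must lie in 0..n", call. = FALSE)
  g <- .gcd(n, k)
  divs <- which((g %% seq_len(max(g, 1L))) == 0L)
  total <- sum(vapply(divs, function(d) .euler_phi(d) * choose(n / d, k / d),
                      numeric(1)))
  as.integer(round(total / n))
}

.gcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

.euler_phi <- function(d) {
  sum(vapply(seq_len(d), function(i) .gcd(i, d) == 1L, logical(1)))
}

#' Enumerate arrangement classes of k ligands on an n-membered ring
#'
#' Enumerates all `C(n, k)` placements, groups them by cyclic rotation and
#' returns one row per distinct canonical form with its orbit size (number
#' of distinct rotations) and random-binding null probability
#' `orbit_size / C(n, k)`.  For k = 2 on an 8-ring this yields the four
#' classes with orbit sizes 8, 8, 8 and 4: the diametrically opposite pair
#' can be realized around the ring in only half as many ways as the others,
#' so its null frequency is half of theirs.
#'
#' @inheritParams count_classes
#' @param symmetry Equivalence group, as in [canonicalize_ring()].  The
#'   default (rotation only) matches a ring viewed from a fixed face with a
#'   defined handedness.
#' @return A data.frame with columns `k`, `canonical` (pattern string such
#'   as `"11000000"`), `orbit_size` and `null_prob`, sorted by `canonical`.
#' @examples
#' enumerate_classes(8, 2)
#' @export
enumerate_classes <- function(n, k, symmetry = c("cyclic", "dihedral")) {
  symmetry <- match.arg(symmetry)
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 1)
  if (k < 0 || k > n) stop("k must lie in 0..n", call. = FALSE)
  if (k == 0) {
    sets <- matrix(integer(0), nrow = 0)
    vecs <- matrix(0L, nrow = 1, ncol = n)
  } else {
    sets <- utils::combn(n, k)
    vecs <- t(apply(sets, 2L, function(s) {
      v <- integer(n); v[s] <- 1L; v
    }))
  }
  keys <- apply(vecs, 1L, function(v) .ring_string(canonicalize_ring(v, symmetry)))
  tab <- table(keys)
  out <- data.frame(
    k = as.integer(k),
    canonical = names(tab),
    orbit_size = as.integer(tab),
    null_prob = as.integer(tab) / choose(n, k),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random-binding null pmf over arrangement classes
#'
#' @inheritParams enumerate_classes
#' @return Named numeric vector: canonical pattern string -> probability
#'   `orbit_size / C(n, k)`; sums to 1.
#' @export
null_arrangement_pmf <- function(n, k, symmetry = c("cyclic", "dihedral")) {
  cls <- enumerate_classes(n, k, symmetry)
  stats::setNames(cls$null_prob, cls$canonical)
}

#' Hypergeometric null for an inter-ring (trans-equator) subunit pair
#'
#' Under random placement of `m` bound nucleotides over all `N` sites of a
#' particle, the number `j` of bound sites in a designated 2-site trans-ring
#' pair follows `P(j) = C(2, j) * C(N - 2, m - j) / C(N, m)`, `j = 0, 1, 2`.
#'
#' @param N Total sites per particle (16 for a 2x8 complex).
#' @param m Total bound sites, `0 <= m <= N`.
#' @return List with `N`, `m` and `pmf` (named vector over j = 0, 1, 2).
#' @export
interring_pair_null <- function(N, m) {
  stopifnot(length(N) == 1L, length(m) == 1L, N >= 2)
  if (m < 0 || m > N) stop("m must lie in 0..N", call. = FALSE)
  j <- 0:2
  pmf <- choose(2, j) * choose(N - 2, m - j) / choose(N, m)
  pmf[is.na(pmf) | pmf < 0] <- 0
  list(N = as.integer(N), m = as.integer(m),
       pmf = stats::setNames(pmf, as.character(j)))
}

#' Hypergeometric null for the split of m bound sites across the two rings
#'
#' Under random placement of `m` nucleotides over `N = 2 * ring_size` sites,
#' the occupancy `kA` of one designated ring follows
#' `P(kA) = C(ring_size, kA) * C(ring_size, m - kA) / C(N, m)`.
#'
#' @param N Total sites; must equal `2 * ring_size`.
#' @param m Total bound sites.
#' @param ring_size Sites per ring (default 8).
#' @return Named numeric vector over `kA = 0..ring_size` (exact zeros where
#'   infeasible); sums to 1.
#' @export
ring_split_null <- function(N, m, ring_size = 8) {
  stopifnot(length(N) == 1L, length(m) == 1L)
  if (2 * ring_size != N) stop("N must equal 2 * ring_size", call. = FALSE)
  if (m < 0 || m > N) stop("m must lie in 0..N", call. = FALSE)
  kA <- 0:ring_size
  pmf <- choose(ring_size, kA) * choose(ring_size, m - kA) / choose(N, m)
  pmf[is.na(pmf) | pmf < 0] <- 0
  stats::setNames(pmf, as.character(kA))
}

# Exact pmf of the number d of fully occupied in-register pairs when m bound
# sites are placed uniformly over the 8 two-site trans-ring pairs (16 sites):
# P(d) = C(8, d) C(8 - d, m - 2d) 2^(m - 2d) / C(16, m).  The per-particle
# (j = 0, 1, 2) pair tally is the deterministic function
# (8 - m + d, m - 2d, d) of d, which makes particle-level resampling of the
# random-placement null a multinomial draw over d.
.pair_double_pmf <- function(m, n_pairs = 8L) {
  N <- 2L * n_pairs
  stopifnot(m >= 0, m <= N)
  d <- max(0L, m - n_pairs):(m %/% 2L)
  pmf <- choose(n_pairs, d) * choose(n_pairs - d, m - 2 * d) *
    2^(m - 2 * d) / choose(N, m)
  stats::setNames(pmf, as.character(d))
}

#' Export the full arrangement-class table for an n-ring as TSV
#'
#' Writes one row per class for every `k` in `0..n` with columns `k`,
#' `canonical_string`, `orbit_size`, `null_prob`.
#'
#' @param path Output TSV path.
#' @param n Ring size (default 8).
#' @inheritParams enumerate_classes
#' @return The table, invisibly.
#' @export
write_class_table <- function(path, n = 8, symmetry = c("cyclic", "dihedral")) {
  symmetry <- match.arg(symmetry)
  tabs <- lapply(0:n, function(k) enumerate_classes(n, k, symmetry))
  tab <- do.call(rbind, tabs)
  names(tab)[names(tab) == "canonical"] <- "canonical_string"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
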