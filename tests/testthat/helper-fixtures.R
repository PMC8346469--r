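# Shared fixtures and independent oracles, built in code.

# All 256 binary occupancy vectors of length 8 as a matrix.
all_rings8 <- function() {
  t(vapply(0:255, function(x) as.integer(intToBits(x)[1:8]), integer(8)))
}

# Independent oracle for rotational equivalence: the full set of rotations
# of a vector, computed by explicit shifting (no package internals).
oracle_rotations <- function(v) {
  n <- length(v)
  lapply(seq_len(n) - 1L, function(r) v[((seq_len(n) - 1L + r) %% n) + 1L])
}

# Independent brute-force count of rotation-distinct (or rotation+reflection
# distinct) classes among all C(n, k) placements.
oracle_count_classes <- function(n, k, reflect = FALSE) {
  if (k == 0) return(1L)
  sets <- utils::combn(n, k)
  seen <- character(0)
  cnt <- 0L
  for (i in seq_len(ncol(sets))) {
    v <- integer(n); v[sets[, i]] <- 1L
    key <- paste(v, collapse = "")
    if (key %in% seen) next
    cnt <- cnt + 1L
    orbit <- oracle_rotations(v)
    if (reflect) orbit <- c(orbit, oracle_rotations(rev(v)))
    seen <- c(seen, vapply(orbit, paste, character(1), collapse = ""))
  }
  cnt
}

# Build a particle_set directly from a ring-occupancy matrix (n_rings x 8):
# rings are paired consecutively (rows 1+2 form particle 1, etc.); bound
# subunits get class 5, unbound class 1.  Odd row counts get a final
# unpaired particle whose second ring is omitted (left missing).
ps_from_occ <- function(occ) {
  n_rings <- nrow(occ)
  recs <- data.frame(
    rlnImageName = sprintf("p%04d", rep(ceiling(seq_len(n_rings) / 2), each = 8L)),
    occRingIndex = rep((seq_len(n_rings) + 1L) %% 2L, each = 8L),
    occSubunitPosition = rep(0:7, times = n_rings),
    occClassId = ifelse(as.integer(t(occ)) == 1L, 5L, 1L)
  )
  assemble_particles(recs, class_map())
}

# Repeat each row of `pat` (a list of 0/1 vectors) `times` times.
occ_of_patterns <- function(pat, times) {
  do.call(rbind, mapply(function(p, t) {
    matrix(rep(as.integer(p), t), nrow = t, byrow = TRUE)
  }, pat, times, SIMPLIFY = FALSE))
}

# A small particle-level STAR table with Euler angles, for expansion tests.
particle_star_fixture <- function(n = 3) {
  data.frame(
    rlnImageName = sprintf("img_%03d.mrc", seq_len(n)),
    rlnAngleRot = seq(-50, 310, length.out = n) %% 360,
    rlnAngleTilt = seq(10, 170, length.out = n),
    rlnAnglePsi = seq(5, 355, length.out = n)
  )
}
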