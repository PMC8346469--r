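# Symmetry-expansion bookkeeping and per-particle state assembly.
#
# The focused-classification workflow replicates each particle's metadata
# record once per symmetry-related orientation: x2 for the two rings of the
# double-ring complex (D1 expansion) and x8 for the eight subunit positions
# within a ring (C8 expansion).  These functions reproduce that bookkeeping
# on STAR tables and reassemble the per-particle 2x8 occupancy state from
# the resulting subunit-level class assignments.

.norm_angle <- function(a) ((a %% 360) + 360) %% 360

#' Ring-level (x2) symmetry expansion of a particle table
#'
#' Emits exactly two rows per input particle row, `occRingIndex` 0 and 1.
#' Ring 1 carries the flip-equivalent orientation: tilt becomes
#' `180 - tilt`, rot becomes `-rot`, psi becomes `psi + 180`, all normalized
#' to `[0, 360)`.  Ring 0 rows are the input rows unchanged, so
#' [collapse_expansion()] inverts this exactly.
#'
#' @param tab Particle-level data.frame (no `occRingIndex` column).
#' @return Ring-level data.frame with `2 * nrow(tab)` rows.
#' @export
expand_rings <- function(tab) {
  stopifnot(is.data.frame(tab))
  if ("occRingIndex" %in% names(tab)) {
    stop("table already carries occRingIndex; it is ring-level", call. = FALSE)
  }
  r0 <- tab
  r1 <- tab
  if ("rlnAngleTilt" %in% names(r1)) r1$rlnAngleTilt <- .norm_angle(180 - r1$rlnAngleTilt)
  if ("rlnAngleRot" %in% names(r1)) r1$rlnAngleRot <- .norm_angle(-r1$rlnAngleRot)
  if ("rlnAnglePsi" %in% names(r1)) r1$rlnAnglePsi <- .norm_angle(r1$rlnAnglePsi + 180)
  out <- rbind(r0, r1)
  out$occRingIndex <- rep(c(0L, 1L), each = nrow(tab))
  ord <- order(rep(seq_len(nrow(tab)), 2L), out$occRingIndex)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "star_block") <- attr(tab, "star_block")
  out
}

#' Subunit-level (x8) symmetry expansion of a ring table
#'
#' Emits exactly eight rows per input ring row, `occSubunitPosition`
#' `j = 0..7`, with `rlnAngleRot` incremented by `j * 45` degrees
#' (normalized to `[0, 360)`); position 0 rows are unchanged.
#'
#' @param tab Ring-level data.frame (has `occRingIndex`, no
#'   `occSubunitPosition`).
#' @return Subunit-level data.frame with `8 * nrow(tab)` rows.
#' @export
expand_subunits <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (!"occRingIndex" %in% names(tab)) {
    stop("table is not ring-level (occRingIndex missing); expand_rings first",
         call. = FALSE)
  }
  if ("occSubunitPosition" %in% names(tab)) {
    stop("table already carries occSubunitPosition; it is subunit-level",
         call. = FALSE)
  }
  n <- nrow(tab)
  out <- tab[rep(seq_len(n), each = 8L), , drop = FALSE]
  out$occSubunitPosition <- rep(0:7, times = n)
  if ("rlnAngleRot" %in% names(out) && n > 0L) {
    j <- out$occSubunitPosition
    keep <- j == 0L
    out$rlnAngleRot <- ifelse(keep, out$rlnAngleRot,
                              .norm_angle(out$rlnAngleRot + 45 * j))
  }
  rownames(out) <- NULL
  attr(out, "star_block") <- attr(tab, "star_block")
  out
}

#' Collapse a symmetry expansion back to its parent table
#'
#' Inverts [expand_subunits()] (when `occSubunitPosition` is present) or
#' [expand_rings()] by selecting the index-0 rows, whose angles were never
#' modified, and dropping the expansion column.
#'
#' @param tab Ring- or subunit-level data.frame.
#' @return The parent-level data.frame.
#' @export
collapse_expansion <- function(tab) {
  stopifnot(is.data.frame(tab))
  if ("occSubunitPosition" %in% names(tab)) {
    out <- tab[tab$occSubunitPosition == 0L, , drop = FALSE]
    out$occSubunitPosition <- NULL
  } else if ("occRingIndex" %in% names(tab)) {
    out <- tab[tab$occRingIndex == 0L, , drop = FALSE]
    out$occRingIndex <- NULL
  } else {
    stop("table carries no expansion column to collapse", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "star_block") <- attr(tab, "star_block")
  out
}

#' Declare which conformational classes are nucleotide-bound
#'
#' Partition of the class universe into bound, unbound and excluded classes.
#' The default encodes the focused-classification result for the 2x8
#' chaperonin: nucleotide density is present in the four more-closed subunit
#' conformations (classes 5-8) and absent in the four more-open ones
#' (classes 1-4); two poorly resolved classes (9, 10) are excluded from
#' arrangement analyses.
#'
#' @param bound,unbound,excluded Disjoint integer class-id sets.
#' @return An object of class `"class_map"`.
#' @export
class_map <- function(bound = 5:8, unbound = 1:4, excluded = 9:10) {
  bound <- as.integer(bound); unbound <- as.integer(unbound)
  excluded <- as.integer(excluded)
  all3 <- c(bound, unbound, excluded)
  if (anyDuplicated(all3)) {
    stop("bound, unbound and excluded class sets must be disjoint", call. = FALSE)
  }
  structure(list(bound = bound, unbound = unbound, excluded = excluded,
                 universe = sort(all3)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> bound: {", paste(x$bound, collapse = ","),
      "}  unbound: {", paste(x$unbound, collapse = ","),
      "}  excluded: {", paste(x$excluded, collapse = ","), "}\n", sep = "")
  invisible(x)
}

.std_subunit_cols <- function(records) {
  alias <- c(particle_id = "rlnImageName", ring_index = "occRingIndex",
             position = "occSubunitPosition", class_id = "occClassId")
  for (nm in names(alias)) {
    if (!alias[[nm]] %in% names(records) && nm %in% names(records)) {
      names(records)[names(records) == nm] <- alias[[nm]]
    }
  }
  miss <- setdiff(unname(alias), names(records))
  if (length(miss)) {
    stop("subunit records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records
}

#' Assemble per-particle occupancy states from classified-subunit records
#'
#' Maps each subunit's 3D-class assignment back to its (particle, ring,
#' position) slot and derives the ring occupancy bit via the class map
#' (1 iff the class is in `bound`).  Rings with any excluded-class subunit
#' or any missing position are flagged (`"has_excluded"` /
#' `"missing_subunit"`) and are dropped from arrangement statistics by the
#' analysis functions, but remain in the object for provenance accounting.
#' A particle is `paired` when both of its rings are complete.
#'
#' @param records Subunit-level data.frame with columns `rlnImageName`,
#'   `occRingIndex`, `occSubunitPosition`, `occClassId` (the aliases
#'   `particle_id`/`ring_index`/`position`/`class_id` are also accepted).
#' @param map A [class_map()].
#' @return An object of class `"particle_set"`: list with `rings`
#'   (per-ring accounting data.frame: `particle_id`, `ring_index`, `status`,
#'   `complete`, `k`, `paired`), `occ` and `conf` (`n_rings x 8` matrices of
#'   occupancy bits and class ids, `NA` at missing positions) and the
#'   `class_map` used.
#' @export
assemble_particles <- function(records, map = class_map()) {
  stopifnot(inherits(map, "class_map"))
  records <- .std_subunit_cols(records)
  cls <- records$occClassId
  unknown <- setdiff(unique(cls), map$universe)
  if (length(unknown)) {
    stop("class id(s) absent from class map: ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  }
  pid <- as.character(records$rlnImageName)
  ring <- as.integer(records$occRingIndex)
  pos <- as.integer(records$occSubunitPosition)
  if (any(ring < 0L | ring > 1L)) stop("occRingIndex must be 0 or 1", call. = FALSE)
  if (any(pos < 0L | pos > 7L)) stop("occSubunitPosition must be in 0..7", call. = FALSE)

  upid <- unique(pid)
  ring_key <- paste(rep(upid, each = 2L), rep(0:1, length(upid)), sep = "\r")
  row_of <- match(paste(pid, ring, sep = "\r"), ring_key)
  n_rings <- length(ring_key)
  conf <- matrix(NA_integer_, n_rings, 8L)
  conf[cbind(row_of, pos + 1L)] <- cls
  occ <- matrix(NA_integer_, n_rings, 8L)
  occ[!is.na(conf)] <- as.integer(conf[!is.na(conf)] %in% map$bound)
  occ[conf %in% map$excluded] <- NA_integer_

  n_present <- rowSums(!is.na(conf))
  n_excl <- rowSums(matrix(conf %in% map$excluded, n_rings, 8L))
  status <- ifelse(n_excl > 0L, "has_excluded",
                   ifelse(n_present < 8L, "missing_subunit", "complete"))
  complete <- status == "complete"
  k <- ifelse(complete, rowSums(occ), NA_integer_)
  rings <- data.frame(
    particle_id = rep(upid, each = 2L),
    ring_index = rep(0:1, length(upid)),
    status = status,
    complete = complete,
    k = as.integer(k),
    stringsAsFactors = FALSE
  )
  both_ok <- tapply(complete, rings$particle_id, all)[upid]
  rings$paired <- rep(unname(both_ok), each = 2L)

  structure(list(rings = rings, occ = occ, conf = conf, class_map = map),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  acc <- table(factor(x$rings$status,
                      levels = c("complete", "has_excluded", "missing_subunit")))
  cat(sprintf("<particle_set> %d particles, %d rings (%d complete, %d has_excluded, %d missing_subunit); %d paired particles\n",
              length(unique(x$rings$particle_id)), nrow(x$rings),
              acc[["complete"]], acc[["has_excluded"]], acc[["missing_subunit"]],
              sum(x$rings$paired & x$rings$ring_index == 0L)))
  invisible(x)
}

#' Ring-accounting summary of a particle set
#'
#' @param ps A `particle_set`.
#' @return Named integer vector: total, complete, has_excluded,
#'   missing_subunit, paired_particles.
#' @export
ring_accounting <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  st <- ps$rings$status
  c(total = nrow(ps$rings),
    complete = sum(st == "complete"),
    has_excluded = sum(st == "has_excluded"),
    missing_subunit = sum(st == "missing_subunit"),
    paired_particles = sum(ps$rings$paired & ps$rings$ring_index == 0L))
}

# Occupancy matrix of complete rings only.
.complete_occ <- function(ps) {
  ps$occ[ps$rings$complete, , drop = FALSE]
}

# Paired-particle occupancy: list of two aligned n_pairs x 8 matrices
# (ring 0 and ring 1) for particles whose rings are both complete.
.paired_occ <- function(ps) {
  ok <- ps$rings$paired
  a <- ps$occ[ok & ps$rings$ring_index == 0L, , drop = FALSE]
  b <- ps$occ[ok & ps$rings$ring_index == 1L, , drop = FALSE]
  list(ring0 = a, ring1 = b)
}

#' Export assembled particle states as TSV
#'
#' One row per ring: particle id, ring index, status, k and the occupancy
#' and conformation strings.
#'
#' @param ps A `particle_set`.
#' @param path Output TSV path.
#' @return The exported data.frame, invisibly.
#' @export
write_particle_states <- function(ps, path) {
  stopifnot(inherits(ps, "particle_set"))
  occ_str <- apply(ps$occ, 1L, function(v) paste(ifelse(is.na(v), ".", v), collapse = ""))
  conf_str <- apply(ps$conf, 1L, function(v) paste(ifelse(is.na(v), ".", v), collapse = ","))
  out <- cbind(ps$rings, occupancy = occ_str, conformations = conf_str)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
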