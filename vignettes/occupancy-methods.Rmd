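---
title: "Methods: ring occupancy combinatorics and cooperativity tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ring occupancy combinatorics and cooperativity tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringocc)
```

## The statistical model

A double-ring chaperonin particle has `N = 16` nucleotide-binding sites in
two stacked 8-membered rings.  Focused classification assigns each subunit
a conformational class; a class map partitions classes into
nucleotide-bound, unbound and excluded (poorly resolved) sets, so each
ring yields a length-8 binary occupancy vector.

The null hypothesis throughout is **random binding**: conditional on `k`
bound subunits in a ring, every one of the `C(8, k)` placements is equally
likely; conditional on `m` bound subunits in a particle, every one of the
`C(16, m)` placements is equally likely.  Three families of observables
are tested against this null.

**Intra-ring arrangements.**  Placements are grouped up to cyclic
rotation into binary necklaces ("arrangement classes").  A class with
orbit size `o` (its number of distinct rotations, a divisor of 8) has null
probability `o / C(8, k)`; the class count is Burnside's
`(1/8) * sum_{d | gcd(8,k)} phi(d) * C(8/d, k/d)`.  Equivalence is under
rotation **only**, not reflection: a physical ring viewed from a fixed
face has a defined handedness, and the rotation-only decomposition is the
one whose `k = 2` counts (4 classes, orbits 8, 8, 8, 4) correspond to the
distinguishable spacings of two ligands.  A `symmetry = "dihedral"` flag
is available for sensitivity analysis (it merges reflection-related
classes, e.g. 7 necklaces into 5 bracelets at `k = 3`).  The canonical
class representative is the lexicographically smallest rotation read in
increasing position index — deterministic, cheap and order-independent.
The class counts for `k = 0..8` are 1, 1, 4, 7, 10, 7, 4, 1, 1; only the
`k = 2` case has a printed external reference, so the others are verified
internally by brute-force enumeration against the closed form.

**A one-dimensional adjacency summary.**  The arrangement chi-square
spreads its power over many classes; the statistic
`A = sum_i s_i s_{i+1 mod 8}` (number of adjacent bound-bound edges)
targets the alternative of interest — neighbour coupling — directly.  Its
null pmf at each `k` is computed by exhaustive enumeration of the
`C(8, k)` placements; its null mean is `8 k (k-1) / 56` by linearity of
expectation over edges.

**Inter-ring structure.**  The split of `m` over the two rings and the
occupancy `j = 0, 1, 2` of an in-register trans-equator subunit pair both
have hypergeometric nulls computed with exact binomial coefficients
(converted to doubles once, so normalization identities hold to machine
precision).  Position `i` of ring 0 is paired with position `i` of ring 1
("in-register" stacking, the group II inter-ring geometry); the partner
map is a convention, and the assembly keeps the two rings' position
indices in one fixed rotational direction as seen from a single exterior
viewpoint, matching the C8 expansion index.

## Tests and their conditioning

All tests condition on the observed stratum sizes: the arrangement test
on the number of complete rings at each `k`, the inter-ring tests on each
particle's total `m`.  Conditioning on `m` per particle (rather than on
pooled saturation) removes occupancy-mixture confounding; a
saturation-level view is still emitted descriptively.

The default goodness-of-fit is a **Monte Carlo exact multinomial test**:
Pearson's statistic, with its reference distribution simulated by
resampling class counts from the null multinomial (default 10,000
resamples, fixed seed).  Expected counts per class can be far below
asymptotic validity at extreme `k`, and the Monte Carlo p-value is valid
at any resample count; asymptotic Pearson and G variants remain
selectable.  The global tests sum per-stratum statistics and simulate all
strata jointly, yielding a single p-value.  For the inter-ring pair test
the 8 pairs of a particle are dependent, so the null is simulated at the
particle level; the per-particle pair tally is a deterministic function of
the number `d` of doubly occupied pairs, whose exact pmf
`P(d) = C(8,d) C(8-d, m-2d) 2^(m-2d) / C(16, m)` makes that resampling a
multinomial draw.

Strata with fewer than `min_stratum = 20` rings (particles) are reported
descriptively without p-values — sparse strata are plotted, not tested.
No multiple-testing correction is applied across strata by default, since
the global tests already aggregate; per-stratum p-values are reported
as-is and a Bonferroni pass can be applied by the caller.

The key logical property, checked by the test suite as a negative
control: a concerted (MWC-type) mechanism changes the *distribution of
k*, but places ligands uniformly given `k`, so the conditional-on-k
arrangement and adjacency tests must not reject it above their nominal
level.  Cooperativity of the sequential kind (KNF/Ising) distorts
placements and is detected.

## The synthetic-data generator

The generator stands in for the classified cryoEM particle table: it
emulates per-subunit bound/unbound states under a chosen binding model,
assigns class labels, applies classification noise and emits the same
STAR dialect the pipeline ingests.  Models are equilibrium snapshots — the
experiment it emulates flash-freezes the complex immediately after mixing
with ATP, so no hydrolysis kinetics are modelled — and ADP/ATP are not
distinguished (a single "nucleotide-bound" state).

Parameters, defaults and rationale:

* `independent`: `p = 0.5` per site.  The default saturation regime
  echoes the experimental stoichiometry of one ATP per two subunits
  (8 ATP per 16-subunit complex), i.e. expected fractional saturation
  about one half.
* `ising`: fields/couplings `h, J, K` in natural-log units
  (`h = J = K = 0` reduces to `p = 0.5`).  Sampling is by exact
  enumeration of the Gibbs distribution — all `2^8` ring configurations
  when `K = 0`, all `2^16` particle configurations otherwise — so the
  sampler is exact, not approximate.
* `mwc`: per ring, `(state, k)` is drawn with weights
  `W(R,k) = C(8,k) alpha^k`, `W(T,k) = L C(8,k) (c alpha)^k`, then the
  `k` ligands are placed uniformly; rings are independent.  Defaults
  `L = 50, c = 0.05, alpha = 1` give a strongly two-state ring with
  moderate saturation; `c = 1` collapses the two states into independent
  binding with `p = alpha / (1 + alpha)`, a reduction the tests use as an
  oracle.
* `knf`: exactly `m_total` ligands (default 8, the stoichiometric
  expectation) are placed sequentially, each step choosing an empty site
  with probability proportional to `exp(beta * bound intra-ring
  neighbours)`.  `beta = 0` is uniform filling; `beta > 0` clusters,
  `beta < 0` disperses.
* noise: a subunit is assigned an excluded class with probability `u`,
  otherwise the wrong bound/unbound group with probability `eps` (both
  marginal rates exactly as stated; one uniform draw per subunit decides).
  No quantitative misclassification rate is available for real focused
  classification, so `eps` and `u` default to 0 and are treated as
  sensitivity parameters.

Determinism: one root seed initializes the RNG and all draws are made in
a fixed vectorized order over particle index, so identical configurations
give byte-identical output tables regardless of how results are iterated.
(A counter-based per-particle substream scheme would give the same
guarantee; R's generators make the vectorized-order contract the simpler
correct choice.)

What the generator does **not** emulate: image formation, projection
geometry, map-space classification errors that correlate across
neighbouring subunits, or class-conditional structure within the bound
and unbound groups (class labels within a group are uniform — the
composition-by-occupancy readout on real data carries information the
generator deliberately does not).  Passing tests therefore validate the
combinatorics, the bookkeeping and the statistical calibration of the
pipeline; they do not validate assumptions about how classification
errors arise in real micrographs, and correlated misclassification could
mimic or mask cooperativity in ways the independent-noise channel cannot
produce.

## Assembly and filtering decisions

Rings containing an excluded-class or missing subunit are dropped from
arrangement statistics and retained in the accounting (no imputation:
imputing states would fabricate arrangement signal).  The run log reports
`complete + has_excluded + missing_subunit = total` at every stage.
Rings are the sampling unit for intra-ring statistics, whether or not
their sibling ring survives filtering; particle-level (inter-ring)
statistics use only particles with both rings complete.  Euler angles are
carried through the x2/x8 expansions for table fidelity (ring 1 takes the
flip-equivalent orientation, subunit `j` adds `j * 45` degrees to rot)
but are never used by the statistics.

## Numerical choices and problem sizes

Orbit probabilities and hypergeometric nulls use exact binomial
coefficients; pmfs sum to 1 to machine precision, which the suite asserts.
Monte Carlo p-values use the `(1 + #{sim >= obs}) / (B + 1)` estimator
(never exactly zero, slightly conservative).  The test suite runs its
calibration and power experiments at 5,000 rings per replicate over 100
seeded replicates with 2,000 Monte Carlo resamples per test — sizes chosen
so that type-I error is measured with a 2.2% binomial standard error and
the whole suite stays inside a desktop-scale run; the 10,000-resample
default applies to ordinary analyses.  Sampler/oracle agreement is
checked in total-variation distance at 100,000 rings (ring-level law) and
30,000 particles (the `2^16` joint law and its occupancy marginal).

## Known limitations

* Homo-oligomeric rings only: sites are interchangeable up to rotation,
  so hetero-oligomeric chaperonins (TRiC/CCT) with distinct paralog
  positions need a different equivalence structure.
* The trans-ring partner map is a configurable convention; if the true
  inter-ring register were staggered, the in-register pair statistics
  would mix partner pairs.
* The arrangement tests are blind to concerted mechanisms by design;
  occupancy-count dispersion comparisons (ring-similarity, occupancy
  histograms against binomial laws) carry that information instead.
* p-values are conditional on the class map; misassignment of a class's
  bound status shifts occupancy systematically, which no within-k test
  can detect.
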