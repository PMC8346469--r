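Package: ringocc
Title: Per-Particle Nucleotide Occupancy Statistics for Double-Ring Chaperonins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs which subunits of a two-by-eight-subunit chaperonin
    particle are nucleotide-bound from focused-classification particle tables,
    and tests intra-ring and inter-ring binding patterns against an explicit
    random-binding combinatorial null. Provides exact binary-necklace
    enumeration of ring ligand arrangements with rotational orbit sizes and
    null probabilities, hypergeometric nulls for inter-ring occupancy, STAR
    particle-table bookkeeping for ring-level and subunit-level symmetry
    expansion, generative binding models (independent, nearest-neighbour
    Ising, concerted MWC, sequential KNF) with a classification-noise
    channel as a synthetic-data generator, and Monte Carlo goodness-of-fit
    tests for cooperativity with power and calibration utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
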