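Package: archaeopop
Title: Population Genetics of Heterochronous Haplotype Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of ancient-DNA haplotype
    data sampled at different points in time (heterochronous sampling), with
    bovine mitochondrial and Y-chromosomal markers as the motivating system.
    Reads pre-aligned sequence fragments addressed by circular reference
    coordinates, collapses them into haplotypes, classifies haplotypes into
    haplogroups from a configurable diagnostic-site rule set, computes the
    classical diversity suite (segregating sites, haplotype diversity, mean
    pairwise differences, nucleotide diversity, Watterson's theta, Tajima's D
    with beta-approximation significance) together with a heterochrony
    correction for nucleotide diversity, builds median-joining haplotype
    networks, and runs Pearson chi-square and two-tailed Fisher exact tests
    on temporal and geographic cohort tables.  A serial-coalescent simulator
    and cohort-panel generators provide synthetic data with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
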