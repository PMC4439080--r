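---
title: "Analysing heterochronous haplotype samples with archaeopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing heterochronous haplotype samples with archaeopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archaeopop)
```

## The problem

Ancient-DNA population studies compare haplotype composition and genetic
diversity across samples that differ in age by centuries to millennia.
The motivating system is domestic cattle from the northern Baltic Sea
region: short mitochondrial fragments (a 486 bp D-loop segment at
positions 16031--178 of the circular bovine reference V00654, a 181 bp
ND5 segment at 12911--13091, jointly a 667 bp haplotype region) plus a
155 bp intron fragment of the Y-chromosomal *UTY* gene whose single
transversion separates the paternal haplotypes Y1 and Y2.  The analysis
chain is generic, however: any aligned haplotype data with per-sample
ages, periods and locations fits.

Three methodological points need care, and they drive the design of this
package:

1. **Heterochronous sampling biases diversity estimators.**  Two
   sequences sampled 2,000 years apart accumulate extra substitutions
   along the time gap, so pooled nucleotide diversity overestimates the
   population parameter.
2. **Haplogroup assignment is a nomenclature, not an inference.**
   Labels follow published diagnostic positions, which change as
   reference panels grow; the classifier must therefore be configuration
   driven.
3. **Cohort counts are small.**  Frequency comparisons need exact tests
   where expected counts are small, with an explicit selection rule.

## Model and procedures

### Coordinates and haplotypes

All positions are 1-based on a circular reference; a region may wrap the
origin once (the D-loop does).  Haplotypes are collapsed under complete
deletion: every column carrying a gap or `N` in any sequence is removed
before comparison, which matches the convention of the standard
haplotype software and keeps the identity $\pi = K/L$ exact on the
retained length $L$.  Labels `H01, H02, ...` are assigned canonically
(descending count, ties by lexicographically smaller sequence), so the
labelling is invariant under sample order.

### Diversity suite

For $n$ sequences with $S$ segregating sites (indel/missing columns
excluded), $h$ distinct haplotypes with frequencies $p_i$, and mean
pairwise difference $K$:

* haplotype diversity $H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$,
* Watterson's estimator $\hat\theta_W = S / a_1$, $a_1 = \sum_{i=1}^{n-1} 1/i$,
* nucleotide diversity $\pi = K/L$,
* Tajima's statistic
  $D = (K - S/a_1) \big/ \sqrt{e_1 S + e_2 S(S-1)}$ with the standard
  $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants.

Significance of $D$ uses the beta approximation of its null
distribution: a scaled beta with mean 0 and variance 1 supported on
$[D_{\min}, D_{\max}]$, where $D_{\min} = (2/n - 1/a_1)/\sqrt{e_2}$ and
$D_{\max} = ((n+1)/(2n) - 1/a_1)/\sqrt{e_2}$, two-sided.  This matches
the approach of the classical implementations; a simulation-based p
could be substituted but was not needed at the package's problem sizes.

### Heterochrony correction

With per-sample ages $t_i$ (years BP) and mean pairwise age gap
$\bar{\Delta t} = \frac{2}{n(n-1)} \sum_{i<j} |t_i - t_j|$, a per-site
per-year mutation rate $r$ inflates pairwise diversity by $c = r \,
\bar{\Delta t}$ per site in expectation (each pair accumulates
substitutions along the unmatched stretch of branch equal to its age
difference).  The corrected estimate is $\pi_{h\mu} = \pi - c$, with
relative bias $(\pi - \pi_{h\mu})/\pi_{h\mu} \times 100\%$.  Rates are
quoted in percent per million years (conventional values 34--53% for the
cattle D-loop; both 43% and 53% appear as reporting conventions, with
generation lengths of 7 and 5 years respectively).  Because the
literature is ambiguous about whether such a rate is meant per site or
per fragment, and per year or per generation, the interpretation is an
explicit argument (`per = "site_year"` default, `"fragment_year"`,
`"site_generation"`); the default is the interpretation under which the
correction's magnitude is validated by the serial-coalescent simulation
below.  A correction driving $\pi_{h\mu}$ negative is clamped to zero
with a warning; that only happens when the assumed rate is inconsistent
with the observed diversity.  Samples dated only by an archaeological
context range get a uniform draw within the range (the range states
bounds, nothing more), seeded for reproducibility.

### Haplogroup classification

The rule set is data: rows of `label`, `parent`, and `position=base`
requirements.  A child inherits all ancestral requirements and may not
contradict them (validated at load).  Classification returns the deepest
rule whose full requirement set matches exactly.  Conservative handling
for damaged ancient DNA: a required site covered by `N`, a gap, or an
IUPAC ambiguity that merely includes the required base leaves the rule
uncontradicted but cannot advance depth.  A sequence covering none of
the diagnostic positions is `unassigned`; a covered profile that
contradicts every rule is also `unassigned` (its allele lies outside the
configured nomenclature) while an uncontradicted profile falls back to
the rule set's default label (`T3`, the reference cluster, in the
shipped set).  Only the T/Q split at position 15953 of the shipped
default is anchored in routinely available primary literature; the other
site/allele entries are internally consistent placeholders and the file
is meant to be replaced with curated values for real analyses.  The Y
allele-to-label mapping is likewise configuration (default G→Y2, T→Y1).

### Median-joining network

`build_mjn()` implements the median-joining construction for multistate
sequence data: the $\varepsilon$-relaxed minimum spanning network over
the observed haplotypes (an edge is kept when its length is within
$\varepsilon$ of the minimax connection weight of its endpoints; at
$\varepsilon = 0$ this is exactly the union of all minimum spanning
trees), followed by greedy insertion of consensus (median) vectors of
connected triplets whenever they reduce the total connection cost, and
final pruning of median nodes of degree ≤ 2.  Two numerical choices
matter:

* **Median proposal.**  A triple's consensus is only proposed when every
  column has a majority symbol.  Such a consensus is a true Steiner
  point — it lies on the geodesic between each pair of its triple — so
  inserting it never stretches distances.  Columns where all three
  symbols differ admit no such point, and proposing an arbitrary
  tie-break there can lengthen paths; those triples are skipped.  This
  is the conservative end of the published algorithm family, consistent
  with running the construction at $\varepsilon = 0$.
* **Determinism.**  Haplotypes enter in canonical order and all ties
  (candidate medians with equal cost reduction) resolve by sequence
  order, so permuted input yields an identical network.

The all-MSTs guarantee is checked non-tautologically on the spanning
stage (`min_spanning_network()`) against an exhaustive MST enumeration
oracle on small random instances; after median insertion the same
guarantee holds relative to the network's extended node set by the cycle
property, and the tests verify instead that the connection cost never
exceeds any observed MST's.

### Cohort tests

Pearson's chi-square (uncorrected, $(r-1)(c-1)$ df) for large tables;
two-tailed Fisher exact (sum of hypergeometric probabilities not
exceeding the observed table's) when 20% or more of expected counts fall
below 5 and the table is 2×2.  The published protocol reports the exact
test for all temporal 2×2 Y-haplotype comparisons — including one whose
expected counts would pass the chi-square rule — so the pipeline runs
Fisher on every 2×2 Y table and the selection rule elsewhere.  For
larger sparse tables the chi-square is reported with a caveat recorded
in the result, as exact r×c tests are out of scope.

## What the generators emulate — and what they do not

`simulate_serial_coalescent()` draws a serial-sampling coalescent
genealogy (lineages activate at their ages; pairwise coalescence at rate
$1$ per $2N_e$ generations per pair, so $\theta = 4 N_e \mu L$ and
homochronous $E[K] = \theta$), then Poisson infinite-sites mutations.
`simulate_panel()` plants haplogroup-diagnostic alleles along rule-tree
paths with Poisson private mutations restricted to non-diagnostic sites,
and assigns periods, sexes and Y alleles per plan.  The default panel
shape follows the study conditions: cohort sizes 5/14/26
(Prehistoric/Medieval/Post-Medieval, 45 ancient samples), with T3 and
T3b dominating among haplogroups, and cohort-size 19/26/49 groupings for
the temporal comparison with moderns.

The generators deliberately omit post-mortem damage (deamination),
sequencing error, alignment uncertainty, recombination and population
structure.  Passing tests therefore show that the estimators, the
classifier and the tests behave correctly under the assumed sampling
model — not that real ancient-DNA data meets those assumptions.
Authenticity in the pipeline is replicate-based
(`replication_consensus()`: ≥3 concordant amplifications spanning ≥2
extractions and ≥2 laboratories, all thresholds configurable), mirroring
wet-lab practice rather than damage modelling.

## Problem sizes and reproducibility

All simulations are desk scale by design: panels of ≤ 50 samples over ≤
750 sites, coalescent validations with 200 replicates at $n = 20$, $L =
600$, and test-calibration runs of 2,000 multinomial tables — each suite
completes in seconds to a couple of minutes.  Every stochastic function
takes a mandatory seed and restores the caller's RNG state, so a
pipeline rerun with the same seed is bit-identical (timestamps aside).

## Worked example

```{r example}
plan <- list(
  cohort_sizes = c(Prehistoric = 5, Medieval = 14, "Post-Medieval" = 26),
  haplogroup_freqs = c(T3 = 0.5, T3b = 0.3, T2 = 0.1, Q = 0.1),
  private_rate = 1.5,
  y1_freq = list(Prehistoric = 0.1, Medieval = 0.1, "Post-Medieval" = 0.5))
panel <- simulate_panel(plan, seed = 42)

ht <- collapse_haplotypes(panel$aln)
ht

est <- diversity_estimates(panel$aln, ages = panel$samples$age_bp,
                           rate_pct_per_myr = 43)
est

net <- build_mjn(ht, epsilon = 0)
net

fisher_exact_2x2(rbind(c(1, 7), c(1, 36)))
```

## Known limitations

* The heterochrony correction subtracts an expectation; it does not
  propagate the correction's Monte-Carlo or dating uncertainty into a
  standard error.
* Exact tests beyond 2×2 are not provided; sparse r×c tables fall back
  to chi-square with a recorded caveat.
* The shipped haplogroup rule set is a scaffold with placeholder alleles
  beyond the 15953 split, and the 245 bp common-region coordinates used
  in comparative panels are a configuration parameter, as they are not
  fixed by any single reference.
* The network plot is a convenience; no attempt is made to reproduce
  publication layouts.
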