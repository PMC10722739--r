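---
title: "Methods and design notes for plastigap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plastigap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastigap)
```

plastigap is a toolkit for asking a single question about a small group of
closely related plant taxa: *do the available molecular and ecological data
separate them into distinct species?* It combines four lines of evidence that
are standard in plastome-scale species delimitation — population-genetic
diversity and differentiation, distance-based barcoding gaps, tree-based
monophyly with bootstrap support, and ecological niche overlap — plus tools
for the quadripartite architecture of plastid genomes and a synthetic-data
generator with known ground truth. This vignette records the statistical
model behind each module, the defaults and why they were chosen, and the
limitations the user should keep in mind.

## 1. Sequence model and alignments

All estimators operate on a `species_alignment`: a samples × sites character
matrix over `A`, `C`, `G`, `T`, with `-`, `N` and any other IUPAC symbol
treated as missing, plus a species label per sample. Coordinates inside the
package are 0-based half-open (`extract_region(aln, 100, 700)` takes 600
columns starting at the 101st site); the command-line reports convert to
1-based inclusive coordinates because that is what bench biologists expect
from alignment viewers.

## 2. Nucleotide diversity and sliding windows

Nucleotide diversity is the mean number of pairwise differences per site,

$$\pi = \binom{n}{2}^{-1} \sum_{i<j} \frac{k_{ij}}{L_{ij}},$$

with two conventions for missing data:

* **complete deletion** (default): sites with any missing value are removed
  once, so every pair is compared over the same $L$ sites. This matches the
  convention of the classic Windows programs used in plastome population
  studies and makes $\pi$ exactly decomposable into per-site heterozygosity,
  which the Hudson FST estimator relies on.
* **pairwise deletion**: each pair uses its own valid sites; retains more
  data but mixes denominators.

`sliding_window_pi()` defaults to a 600 bp window sliding by 200 bp. Windows
of a few hundred base pairs are the established compromise for plastomes:
wide enough that a window contains several segregating sites when $\pi$ is of
order $10^{-3}$, narrow enough to localize hotspots to individual
intergenic spacers. `top_variable_regions()` merges overlapping top-ranked
windows so a single hotspot is reported once.

## 3. Differentiation and gene flow

`hudson_fst()` implements the Hudson-style estimator

$$F_{ST} = 1 - \frac{H_w}{H_b},$$

where $H_b$ is the mean pairwise diversity between species and $H_w$ the
within-species diversity, by default averaged with **equal weight per
species** (option `"size"` weights by the number of within-species pairs).
Equal weighting is the default because sampling in herbarium-based studies is
rarely proportional to census size, and unequal $n$ would otherwise let the
better-sampled species dominate $H_w$. The estimator is undefined when
$H_b = 0$ and can be slightly negative when differentiation is absent; both
are surfaced rather than clamped.

Gene flow uses the island-model conversion $N_m = (1 - F_{ST})/(4 F_{ST})$,
defined only for $F_{ST} > 0$. Its assumptions (equilibrium,
island migration, no selection) rarely hold exactly; $N_m$ is reported as
the conventional summary, not as a demographic estimate.

## 4. Distances and the barcoding gap

`distance_matrix()` supports the uncorrected p-distance and the Kimura
2-parameter distance

$$d_{K2P} = -\tfrac{1}{2}\ln\!\big((1-2P-Q)\sqrt{1-2Q}\,\big),$$

with $P$ and $Q$ the transition and transversion proportions, computed with
pairwise deletion (the convention of the common distance-based barcoding
software). When the formula's argument is non-positive the distance is
**saturated**: the package returns `NA` with a warning instead of a clamped
value, because a fabricated large number would silently distort barcode-gap
and neighbour-joining results.

`barcode_gap_test()` applies the strict rule: a species passes when its
smallest interspecific distance exceeds its largest intraspecific distance.
Species with a single sample have no intraspecific distances; they are
reported with `max_intra = 0` and flagged `single_sample = TRUE`, since a
"pass" there is weak evidence.

## 5. Neighbour-joining, bootstrap, and monophyly

`nj_tree()` is a self-contained Saitou–Nei implementation chosen over
delegating to keep the tie-breaking rule explicit: when two joins have equal
$Q$, the pair whose sorted labels come first lexicographically is joined, so
results are reproducible across platforms. Negative branch lengths are
truncated to zero, and internal edges of length below $10^{-12}$ are
collapsed into multifurcations — identical sequences therefore yield a star
tree with no spurious resolved splits.

`bootstrap_supports()` resamples alignment columns with replacement
(a mandatory `seed` makes runs reproducible), rebuilds the tree, and counts
how often each bipartition of the original tree reappears. Supports are
percentages attached to internal nodes. `monophyly_support()` then reports,
per species, whether its samples form a clade and the support of the clade's
subtending edge. The discrimination criterion defaults to **support ≥ 70%**,
the conventional cutoff for "supported" in bootstrap phylogenetics; the
operator is configurable (`op = ">"`) for users who want the strict
inequality. `discrimination_report()` aggregates markers into the familiar
per-marker table of species supports and the percentage of species
discriminated, treating non-monophyly as "not discriminated".

`diagnostic_indels()` searches for gap runs whose presence/absence pattern is
fixed within one species and absent from all others — the
insertion/deletion characters that often separate young plastid lineages
even when substitutions are scarce.

## 6. Plastome quadripartite structure

Plastid genomes are circular with two identical inverted-repeat copies (IRa,
IRb) separating a large and a small single-copy region (LSC, SSC).
`detect_inverted_repeat()` finds the longest inverted repeat by exact k-mer
(k = 25) seed-and-extend between the doubled sequence and its reverse
complement; the doubling makes detection independent of where the circle was
linearized, which the tests verify by rotating planted genomes. Anchors on a
common reverse-complement diagonal are merged and extended, and the result is
accepted only when the two copies plus the two single-copy arcs tile the
circle. By convention the longer single-copy arc is the LSC and the IR copy
at its downstream border is IRb. Coordinates are 0-based with end allowed to
exceed the sequence length when a region wraps the origin.
`structure_table()` formats per-accession rows plus conventional
"min–max" range strings per species.

## 7. Niche overlap

Suitability grids (read and written in the plain-text ESRI ASCII format,
`NODATA_value -9999`) are compared on the intersection of their valid cells
after normalizing each to sum to 1:

$$D = 1 - \tfrac12 \sum_k |p_{x,k} - p_{y,k}|, \qquad
  I = 1 - \tfrac12 \sum_k \big(\sqrt{p_{x,k}} - \sqrt{p_{y,k}}\big)^2 .$$

Both lie in $[0, 1]$ and $I \ge D$ always. `tpl_threshold()` implements the
10th-percentile training-presence rule with the **nearest-rank** definition
$\lceil p n / 100 \rceil$, so the threshold is always an observed suitability
value. `prune_predictors()` removes one member of each predictor pair with
$|r| > 0.8$ (the usual collinearity cutoff in niche modelling), dropping the
lower-contribution variable, processing pairs in decreasing order of $|r|$,
and breaking exact contribution ties alphabetically with a warning.

## 8. The synthetic-data generator

`simulate_alignment()` emulates a three-species plastome study on the fixed
species tree $((B, C), A)$: a star genealogy within each species (crown
depth = expected substitutions/site from the crown to each tip), exact
per-branch Poisson substitution counts, and a Kimura-type substitution
process in which each event is a transition with probability
$\kappa/(\kappa + 2)$. Because counts are exact Poisson draws, the expected
pairwise divergence has the closed form exposed as
`expected_p_divergence()`, giving the tests and the acceptance run an
analytic oracle. Species-diagnostic indels are planted as alignment columns
gapped in all other species.

What the generator deliberately does **not** emulate: recombination (correct
for plastomes, which are effectively non-recombining), rate variation across
sites, incomplete lineage sorting beyond the star-within-species
approximation, and sequencing error.

`triplostegia_preset()` encodes a realistic default design — 17 + 7 + 9
samples; crown depths 0.002 / 0.0001 / 0.0003 so the early-diverging species
holds most of the diversity; stems 0.004 (a), 0.0029 (bc), 0.0017 (b and c);
20 kb of sequence; one 66 bp and one 18 bp diagnostic indel. These values
were calibrated *forward* from the model so that the emergent pattern matches
what is typical of recently diverged plastid lineages: within-species π of
order $10^{-4}$–$10^{-3}$, pairwise $F_{ST}$ near 0.8–0.9 with the sister
pair most differentiated, and 100% bootstrap discrimination from
genome-scale data.

`make_toy_plastome()` plants an exact quadripartite structure (with a guard
that flanking bases never extend the repeat by chance, so the planted IR is
maximal), and `simulate_grid_pair()` builds Gaussian-bump suitability
surfaces whose overlap statistics are recorded at generation time.

## 9. Problem sizes and verification

The test-suite sizes are the package's own choices, balancing statistical
power against a modest runtime: parameter-recovery checks use 20 independent
seeds at 20 kb (π within three Monte-Carlo standard errors of its analytic
expectation), bootstrap discrimination uses 8 kb and 200 replicates, and the
structure tests use a full-size 154.9 kb toy genome. Estimators are also
checked against independent brute-force oracles on hundreds of random small
instances at $10^{-10}$ tolerance, and distances are cross-validated against
a second implementation (`ape::dist.dna`).

## 10. Limitations

* $F_{ST}$ and $N_m$ inherit all island-model caveats; treat $N_m$ as a
  conventional transform of $F_{ST}$, not a migration-rate estimate.
* The K2P saturation policy (return `NA`) means very divergent pairs drop
  out of barcode-gap summaries; this is intentional and warned about.
* IR detection requires an exact repeat of at least `min_len`
  (default 1,000 bp); genuinely degenerate IRs (as in some IR-lacking
  lineages) are reported as `found = FALSE`.
* Niche metrics quantify overlap in projected suitability, not niche
  identity in environmental space; interpretation follows the usual caveats
  of correlative models.
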