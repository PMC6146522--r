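---
title: "Testing whether a cell phenotype is genomically encoded"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether a cell phenotype is genomically encoded}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogeno)
```

`phenogeno` asks a single question three ways: if a cell phenotype (the
motivating case is the sphere-forming, stem-like state of a breast cancer
cell line) were caused by genetic variants, what footprints would those
variants leave in bulk and single-cell sequencing data, and are they there?
This vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic data generator does
and does not establish.

## 1. VAF-increase selection

**Model.** Each variant site carries per-sample reference and alternate
read counts. If carriers of a phenotype-causing variant expand from the
parental population to a phenotype-enriched derivative, the alternate
fraction (VAF) rises. The package tests each site's 2×2 count table with a
two-sided Fisher's exact test (`stats::fisher.test`) and selects sites with
`p < alpha` (default 0.1, no multiple-testing correction — the correction
happens implicitly at the hotspot level) *and* strictly increasing VAF.

**Assumptions.** Reads are independent draws from the sample's allele pool
(binomial sampling), so depth is the only driver of power. At depth 100 a
0.1 → 0.5 shift is detected essentially always; the null leaks about
half the nominal test size (the two-sided p plus a random direction), which
the test suite pins against an exact enumeration of all count tables.

**Choices.**

* *Depth filter* (default 10–200 reads): applied per sample, and a site is
  removed when any sample is out of range. Applying it to pooled depth
  would be the laxer alternative; per-sample is stricter and is what the
  selection's VAF comparison actually needs (both VAFs defined from
  adequate depth).
* *Zero-depth samples*: the VAF is undefined, the site is unevaluable and
  never selected (reported via message).
* *Region masks*: BED intervals (converted to 1-based inclusive at the
  boundary) plus whole excluded chromosomes (mitochondrial, Y, unplaced),
  mirroring standard repeat/segmental-duplication masking.

## 2. Hotspot calling

**Model.** Under a homogeneous Poisson scatter of selected SNVs, the
distance between adjacent sites within a chromosome is exponential with
rate `lambda = 1/xbar`, `xbar` being the mean adjacent-pair distance over
the whole genome (a single global fit — local rate variation is exactly the
signal being sought, so it must not be absorbed into the null). A distance
has `p_exp = 1 - exp(-lambda * x)`; `p_exp < 0.01` marks it unexpectedly
short. Equivalently, distances below `-xbar * log(0.99)` (about 1% of the
mean) are significant.

**Segmentation.** The per-chromosome flag sequence is run-length encoded
and scanned left to right. A candidate block starts at a significant run
and greedily absorbs following (gap, significant run) pairs while its total
gap count stays within `max_gap_n` (default 1). Blocks therefore begin and
end with significant distances: a leading or trailing gap would extend the
genomic span without adding evidence. A block with at least `min_m`
(default 5) significant distances is emitted and the scan resumes after it,
so emitted hotspots never overlap; a failing candidate only advances the
scan to its second significant run, so a valid window that starts inside a
failed candidate is still found. The test suite proves this scan identical
to an exhaustive enumeration of all maximal windows (leftmost-start,
longest-window tie-break) on every boolean sequence up to length 12 and on
random length-50 sequences.

**Significance.** A hotspot with `m` significant and `n` gap distances,
in a genome with `a` distances of which `b` are significant, is scored by
the hypergeometric upper tail `P(X >= m)` for a draw of `n + m` distances.
The tail is summed directly in log space (log-gamma binomial coefficients
with `logsumexp`), which remains accurate for very small tails where
`1 - CDF` would lose all precision; tests compare it with exact-rational
reference values and with `stats::dhyper` summation across a dense grid.
The span cap (default 100,000 bp, measured first-to-last member SNV,
without the +1 convention) discards blocks that owe their composition to a
single long permissive gap.

**A calibration fact worth knowing.** Detection requires in-cluster
spacing below roughly 1% of the genome-wide mean spacing. With a background
of `r` SNV/bp and `S` total sites on a genome of length `L`, a planted
cluster at rate multiplier `M` has mean spacing `1/(Mr)` and the cutoff is
about `0.01 L/S`; solving gives `M` of order `100 S / (rL)` — for a
10⁷ bp genome at 10⁻⁵/bp (≈100 background sites), multipliers below
roughly 200–400× are *invisible in principle*, however many sites the
cluster holds. The recovery tests therefore demonstrate parameter recovery
at 500× (2 kb clusters, ≈10 sites each), where sensitivity and precision
both exceed 90%.

## 3. Single-cell concordance

**Counts and weights.** At each panel position and cell: total count `TC`,
major count `MC` (the most supported base), background `BC = TC - MC`, and
the base-weight vector `counts/TC`. Weight vectors drive two descriptive
measures — Pearson correlation of concatenated weights between cells, and
the per-position *genetic distance*.

**Genetic distance.** The source formula for the distance places the
square outside the sum of weight differences; read literally that is
`sqrt((sum_n (w1n - w2n))^2)`, which is identically zero because each
weight vector sums to one. Since the quantity is explicitly called a
Pythagorean distance, the package implements the Euclidean form
`sqrt(sum_n (w1n - w2n)^2)`, ranging 0 to √2. The literal reading is
degenerate and is not exposed.

**Error model and PBC.** The reference (non-phenotype) cells estimate a
per-position error rate `PER = sum(BC)/sum(TC)`. Because `PER` is a noisy
estimate from finite reads, the null probability is inflated:
`p0 = PER + c * sqrt(PER/TC_ref)` with `c = qnorm(0.95)` (≈1.64). The
denominator `TC_ref` is ambiguous in the source (no summation sign); the
package defaults to the *mean* reference total count — the scale of a
single cell's coverage — with `tc_ref = "sum"` available. The test group's
per-cell-scale background (`round(sum(BC)/k)` successes out of
`round(sum(TC)/k)` trials, `k` test cells, rounding half away from zero
since banker's rounding would silently perturb counts) is tested against
`Binomial(trials, p0)`, upper tail. Two guards:

* `trials = 0` positions are skipped and logged;
* `p0` is floored at `1/(sum(TC_ref) + 1)`, so a clean reference
  (`PER = 0`) can never certify an observed background count as
  *impossible* — finite data cannot exclude rates below ~1/reads.

**Permutation and CPR.** All `choose(5, 2) = 10` reference/test
relabelings are enumerated; 9 are permutation groups. For each scheme and
each threshold `t` in a grid on [0, 0.1] (default 101 points), `NP` counts
positions with `PBC < t`, and `CPR = NP_case/(NP_perm + NP_case)` compares
the true grouping with each permutation. `0/0` is reported as missing, not
as 0.5 — an undefined ratio is not evidence of symmetry.

**What CPR can and cannot show.** Under the null, defined CPR entries
hover around 0.5, but at deep coverage the corrected binomial test is
conservative (a 10,000-position panel at 4000× with 0.5% error typically
flags only tens of positions below p = 0.1), so per-threshold counts are
small and individual CPR values are coarse; calibration statements should
average over thresholds, permutations and replicate panels. Conversely,
with a variant at fraction 0.5 in *all three* test cells, permutation
schemes whose reference pair contains exactly one carrier estimate
`PER ≈ 0.25` while their two-carrier test triple observes ≈ 1/3 — still
overwhelmingly significant — so such positions are flagged by 6 of the 9
permutations as well, and CPR saturates near 0.7 rather than 1. The
statistic cleanly separates *noise* from *shared signal*, but a fraction-0.5
variant homogeneously present in one group is partially visible to relabeled
groupings by construction. Only the three permutations whose reference pair
holds two carriers absorb the variant entirely (CPR = 1 against them).

## 4. The synthetic worlds

`simulate_snv_positions` draws a homogeneous Poisson process per
chromosome, with planted intervals at multiplied rate (positions
deduplicated, a negligible perturbation at the simulated densities).
`simulate_paired_counts` draws per-site, per-sample depths from an
over-dispersed negative binomial (mean 100 at WGS scale; `Inf` dispersion
gives fixed depth) and binomial alternate counts at the sample's VAF.
`simulate_base_count_matrix` emulates deep amplicon single-cell panels:
mean depth 4000 (the scale of the motivating study's panels), per-position
error rates drawn once from a Beta with mean 0.005 and shared across cells
(error is a property of the position — sequence context, amplification —
not of the cell), errors split uniformly over the three non-major bases,
and optional planted variants at a stated allele fraction in chosen cells.
An allele-dropout knob removes planted variants per cell with stated
probability; it defaults to 0 because no source-derived value exists for
whole-genome-amplification dropout.

What the generators deliberately do **not** model: read-level artifacts
(mapping, strand bias), amplification chimeras and the heavy spatial
correlation of WGA error, copy-number structure, and indels (downstream
stages consume SNVs only). A green test on these worlds establishes that
the *statistics* behave as designed — calibration under the stated null,
recovery of the stated signal — not that real single-cell panels meet the
binomial error assumptions.

**Reproducibility.** Every generator takes a `seed` and is byte-identical
under it (`withr::with_seed`, single RNG stream per call); truth objects
(`sim_truth()`) carry everything needed to score recovery without
re-deriving it.

## 5. Defaults at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| selection `alpha` | 0.1 | p-value | stated two-condition rule |
| depth filter | [10, 200] | reads/sample | bulk WGS calling regime |
| distance significance | 0.01 | p_exp | clustering cutoff |
| `min_m`, `max_gap_n` | 5, 1 | distances | weakest admissible hotspot; P = 1.988e-4 at a = 30,774, b = 4003 |
| `max_length` | 100,000 | bp | span cap |
| panel depth | 4000 | reads | deep amplicon regime |
| error mean | 0.005 | fraction | typical deep-panel background |
| `c` order | 0.95 | quantile | ≈1.64 inflation of PER |
| Bonferroni family level | 0.001 | p-value | flagged-position threshold 0.001/n |
| CPR thresholds | 101 points on [0, 0.1] | p-value | stated threshold sweep |

## 6. Known limitations

* Dataset-specific counts from the motivating study are not reproducible
  without its raw reads; nothing in the package pretends otherwise.
* The hotspot caller's greedy left-to-right tie-break is one of several
  defensible maximal-block semantics; alternatives (e.g. emitting all
  overlapping maximal windows) would double-count shared runs.
* The binomial background test treats the three test cells as exchangeable
  replicates of one pooled cell; a variant private to a single test cell is
  diluted threefold before testing.
* CPR's ceiling under strong shared signal (≈0.7 for fraction-0.5
  variants, see §3) means "CPR ≈ 0.5 everywhere" is interpretable as
  absence of signal, but the converse mapping from CPR to effect size is
  not monotone near the top of the range.
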