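---
title: "Detecting runs of homozygosity with a windowed Gaussian HMM"
author: "rohmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity with a windowed Gaussian HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small managed populations — captive breeding programmes, reintroduced
herds — accumulate autozygosity: long stretches of the genome where both
haplotypes descend from the same ancestral copy. Runs of homozygosity
(RoH) are the observable footprint of that process, and the fraction of
the autosomes inside RoH (`F_ROH`) is a realized inbreeding coefficient
that, unlike the pedigree expectation `F_PED`, captures Mendelian-sampling
variation and background inbreeding invisible to the studbook. This
package implements the full chain from a multi-sample VCF to RoH calls,
inbreeding estimators, their cross-correlations and cohort comparisons,
together with a synthetic-data generator that provides ground truth for
every stage.

## Model and procedure

### Site filtering

Filtering follows the conventions of a VCFtools-style pipeline on
moderate-coverage (~7x) data. The depth filter acts per genotype: a
genotype covered by fewer than 3 or more than 30 reads is set to missing
at that sample only, because a site can be perfectly callable in the
remaining samples. Site quality (< 30), missingness (> 20% of samples
after depth masking) and minor allele frequency (< 0.02, computed from the
depth-masked genotypes) drop whole sites. The order is fixed: depth
masking first, then the site tests on the masked genotypes. Multi-allelic
records are rejected, not decomposed. Scaffolds must exceed 45 Mb so that
window statistics are estimated on chromosome-scale sequence, and windows
whose mean coverage deviates from the genome-wide mean by more than 1 SD
(on the X-aligned scaffold) or 2 SD (elsewhere) are removed from the
callability mask; the asymmetry targets sex-linked sequence, whose
coverage is systematically shifted in the heterogametic sex.

### Window heterozygosity

Heterozygous genotypes are counted in 150-kb windows advancing by 50 kb
(100-kb overlap), anchored at position 1 of each scaffold; the window
statistic is the ratio of het sites to callable bp in the window.
Overlapping windows are deliberately redundant — adjacent windows share
two-thirds of their sequence and are highly interdependent, which smooths
the observation sequence at the cost of correlated noise; no correction is
applied, matching the method's design. A trailing window running past the
scaffold end is truncated there, and grid windows that would add no new
sequence are not emitted. Windows with zero callable bp carry an undefined
ratio: they are excluded from fitting and decoding and break state runs,
the conservative choice (no RoH is ever asserted across sequence we cannot
see).

### The 3-state Gaussian HMM

Per sample, the window-ratio sequence is modelled by a hidden Markov model
with three Gaussian emission states: the lowest-mean state is the RoH
state; the other two absorb the background heterozygosity and its
fluctuations. Three states rather than two gives the background a second
component, which in practice captures either a low-diversity shoulder of
the background or the partially-overlapping windows at tract boundaries.

* **Initialization.** Emission priors come from 1-D k-means (k = 3,
  deterministic k-means++ seeding under the caller's seed) on windows with
  fewer than 60,000 noncallable bp — gappy windows have noisy ratios and
  would distort the cluster moments. Cluster means, variances and weights
  seed the emission parameters and start probabilities. Transition rows
  are initialized Dirichlet(1,1,1) at random under the same seed.
* **Fitting.** Baum-Welch (EM on forward-backward statistics) with
  per-step scaling, so likelihoods stay finite at any sequence length.
  Scaffolds — and stretches separated by undefined windows — are
  independent observation sequences sharing one parameter set; pooling
  maximizes the data behind each per-sample fit. Both emissions and
  transitions are re-estimated. Iteration stops when the log-likelihood
  improves by less than `tol` (1e-6) or after `max_iter` (1000)
  iterations. The log-likelihood is asserted non-decreasing at every
  iteration; a decrease aborts the fit. Emission variances are floored at
  1e-12 (ratio² units) to survive constant stretches.
* **Decoding.** Viterbi (log-space) by default; per-window posterior
  argmax is available behind `decode = "posterior"`. Exact ties are broken
  toward the lower state index.
* **Segmentation.** Each maximal run of at least 3 consecutive RoH-state
  windows becomes one segment from the start of its first window to that
  start plus `n_windows × step`, inclusive — so an untruncated run of `n`
  windows has length `n × 50,000 + 1` bp and the shortest callable segment
  is exactly 150,001 bp. This attribution is the only one consistent with
  that minimum size given the overlapping geometry (the union of three
  overlapping windows spans 250 kb), and it is applied uniformly: each
  window in a run contributes one step of sequence, plus one bp for the
  inclusive end.

A deliberately naive comparator, `baseline_threshold_caller()`, declares a
window low when its ratio falls below a fixed cutoff (default 1e-4,
roughly the log-scale midpoint between the default background rate
2.4e-4 and the tract rate 1e-5) and applies the same run conventions; the
two callers' per-sample RoH fractions correlate above 0.9 on planted-tract
simulations, mirroring the cross-method comparison such analyses report.

### Inbreeding estimators

* `F_ROH` — merged RoH bp over total autosomal bp.
* `F_HOM` — method-of-moments coefficient from homozygote counts,
  `F = (O − E)/(N − E)`, with the unbiased expected-homozygosity
  correction `E = Σ_i [1 − 2 p_i (1 − p_i) n_i/(n_i − 1)]` over the sites
  where the sample is genotyped (`n_i` = non-missing allele count at site
  i). Sites with fewer than two non-missing alleles are excluded. `F_HOM`
  is negative when the sample is more heterozygous than the panel's
  Hardy-Weinberg expectation.
* `F_PED` — the kinship of the parents, from the recursive tabular method:
  `Θ(x,y) = ½[Θ(sire_x, y) + Θ(dam_x, y)]` for x later in topological
  order, `Θ(x,x) = ½(1 + Θ(sire_x, dam_x))`, founders unrelated and
  noninbred (the standard studbook assumption, overridable via
  `founder_kinship`), unknown parents contributing zero.

Estimators are compared by Spearman rank correlation (pairwise-complete,
so `F_PED` pairs automatically restrict to pedigreed samples) and cohorts
by pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment or
one-way ANOVA with Tukey's HSD.

### Colocalization

Jaccard coefficients on base pairs, `|A∩B|/(|A|+|B|−|A∩B|)`, quantify
pairwise RoH sharing; the empty-vs-empty case is defined as 0 and flagged,
since the pure formula is undefined there. The sharing spectrum (bp by
carrier count) is computed by an interval sweep over run-length encoded
coverage, never per-bp loops, and is tested against a per-bp brute force
on toy genomes.

## The synthetic-data generator

The analysis consumes only per-site het/hom status, so the generator
emulates exactly that sufficient statistic: het sites are a marked Poisson
process at 2.4e-4 per bp outside autozygous tracts (matching the
2.1–2.7e-4 range typical of such datasets) and 1e-5 inside, restricted
to a callability mask with ~25% random gaps (callable fraction ~75%,
matching the study design this emulates). Depth is Poisson(7) per
genotype, mirroring ~7x sequencing so the depth filter is meaningfully
exercised; quality passes unless a configurable fraction of sites is
spiked to fail one filter class each. Genotypes of non-focal samples are
homozygous fills under a Beta(0.5, 0.5) allele-frequency spectrum, which
preserves each sample's het process exactly. Autozygosity comes either
from planted tracts (uniform lengths 0.5–2.5 Mb, placed uniformly without
overlap until the per-sample target fraction is reached within half a mean
tract length) or from gene-dropping founder haplotypes through a pedigree
with Poisson crossovers (default 1e-8 per bp, i.e. 1 cM/Mb), where an
interval is autozygous when both inherited labels coincide — giving
realized IBD with genuine Mendelian-sampling variance.

What the generator does **not** emulate: linkage disequilibrium and
coalescent genealogy between samples (het sites are independent across
samples outside gene-drop autozygosity), mapping and reference bias,
base-calling error, and the cross-species-reference artifacts that make
real calls "putative" RoH. Passing tests therefore demonstrate that the
segmentation machinery recovers the two-rate structure it assumes; they do
not certify performance under reference bias or unusual demography.

## Numerical choices

* Forward-backward uses Rabiner scaling (per-step normalization) —
  algebraically equivalent to log-space recursion and stable for
  arbitrarily long sequences; Viterbi is computed in log space.
* Emission densities are floored at 1e-300 so an outlying window far from
  all states cannot zero an entire forward column.
* Variance floor 1e-12 (ratio² units); k-means clusters of size < 2 take
  the floor with a warning.
* Viterbi ties break toward the lower state index; k-means assignment
  ties break toward the lower-mean centroid (both deterministic).
* All randomness (simulation, transition init, k-means seeding) flows
  from explicit integer seeds; pipeline outputs are byte-identical under
  identical config and seed, and every output header carries the package
  version, a config hash and the seed.

## Problem sizes used in the test suite

The suite exercises the estimators at sizes chosen to make sampling error
negligible relative to the tested tolerances while remaining desk-scale:
planted-tract recovery on 100 Mb genomes (two 50-Mb scaffolds, 5 seeds),
Viterbi-vs-enumeration on 200 random instances of up to 12 windows
(3^12 paths scored exhaustively), kinship against Wright path counting on
pedigrees of up to 12 individuals, Hardy-Weinberg calibration on
50 x 4,000 genotype panels, and gene-drop calibration with 1,000
replicates on a 30-Morgan, 30-chromosome genome.

## Known limitations

* **`F_ROH` is conservatively biased under the segment convention.** A run
  of `n` windows spans `(n−1)·step + width` bp of sequence but is
  attributed `n·step + 1` bp — the attribution that makes the minimum
  segment 150,001 bp — so every contiguous run under-reports by
  `width − step` = 100 kb, plus up to one step of grid alignment per edge.
  With many short tracts this accumulates: at 25% autozygosity in tracts
  of mean 1.5 Mb the expected deficit in `F_ROH` is ~0.02–0.03, and the
  planted-tract acceptance check of |F_ROH − truth| ≤ 0.02 sits exactly on
  this boundary (bp-level F1 stays ≥ 0.94). The bias shrinks in proportion
  to mean tract length and is shared by any caller using this window
  geometry and size convention.
* The middle HMM state can converge onto tract-boundary windows (an
  intermediate-heterozygosity regime that genuinely exists in the data),
  occasionally fragmenting long runs; this is the maximum-likelihood fit,
  not an optimizer artifact — restarts from different transition seeds
  reach the same solution.
* Adjacent windows are statistically dependent (shared sequence); no
  correction is applied, so window-level degrees of freedom are
  overstated wherever they are used descriptively.
* `F_HOM` depends on the panel's allele-frequency estimates; with few
  samples the finite-sample correction keeps it unbiased under HWE, but
  structure in the panel shifts it (it is a within-panel, not absolute,
  coefficient).
* Gene dropping uses a uniform crossover rate without interference; the
  Mendelian-sampling variance it produces is correct to first order but
  hotspots and interference would modulate it.
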