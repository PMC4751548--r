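---
title: "Methods: normalization, QC and genetic analysis of SNP array data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, QC and genetic analysis of SNP array data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snparray)
```

# The data model

Infinium-style genotyping arrays measure, for every SNP, fluorescence in
two channels — one per allele, here labelled A and B.  Upstream software
transforms raw fluorescence so that homozygous samples fall near the axes,
heterozygotes near the diagonal, and the total intensity `R = x + y` is
approximately 1 for a normal diploid call.  `snparray` stores a dataset the
way PLINK does: a markers-by-samples matrix of genotype calls (coded as the
count of B alleles: 0, 1, 2, or `NA`), in parallel with a marker map and a
sample table, plus the optional intensity matrices and the BAF/LRR tracks
derived from them.  The `genotypes()` constructor enforces the invariants —
consistent dimensions and ordering, unique identifiers, legal call codes,
markers sorted by (chromosome, position) — so every downstream function can
assume them.

Two conventions are fixed once and used everywhere.  Dosage counts the
B (alternate) allele, which keeps genotype dosage and B-allele frequency on
the same orientation; display functions can flip to reference-allele counts
where that reads better.  Positions are 1-based and genomic regions are
closed intervals, matching manifest conventions.

# Thresholded quantile normalization and the BAF/LRR tracks

The polar coordinates are `theta = (2/pi) * atan2(y, x)` (0 for pure A
signal, 1 for pure B; the two-argument arctangent makes `x = 0` map to
exactly 1) and `R = x + y`.

The Infinium chemistry has a dye bias between the two channels.  tQN
(`tqn_within()`) removes it by quantile-normalizing the x channel against
the y channel *within* each sample: the target distribution is the mean of
the two sorted channels, each channel is mapped through it by average rank,
and a multiplicative cap bounds how far any value may rise — the normalized
value may not exceed `threshold` (default 1.5) times the raw value, zeros
passing through unchanged.  The cap is what distinguishes tQN from plain
quantile normalization (recovered at `threshold = Inf`): it prevents the
rank mapping from inflating near-zero homozygote channels.  An optional
between-array quantile normalization of each channel
(`quantile_normalize_between()`, off by default) can precede the
within-array step.

BAF and LRR are computed against per-marker cluster positions estimated
from reference samples (`estimate_clusters()`).  The reference intensities
are passed through the *identical* normalization chain first, so the
centroids live on the same scale as the normalized study samples; the
centroid statistic is the median (robust to stray calls), and classes with
fewer than `min_cluster_size = 3` reference calls are imputed — a missing
heterozygote from the midpoint of the homozygote thetas, a missing
homozygote by mirroring the observed one about theta 0.5.  Markers whose
centroid triple cannot be formed, or is not monotone in theta, are excluded
and yield missing BAF/LRR.  Reference and study samples should share the
manifest and be drawn from comparable material: cluster positions computed
on a different marker universe inherit that universe's composition biases.

BAF is the piecewise-linear rescaling of theta anchored at the centroids
(0 at `theta_AA`, 0.5 at `theta_AB`, 1 at `theta_BB`); LRR is
`log2(R / R0)` where `R0` interpolates the centroid (theta, R) pairs at the
observed theta, clamped at the outer clusters so no extrapolation can
produce a negative or exploding reference level.  For a clean diploid
sample the expected LRR is 0 and the expected BAF at heterozygous calls is
0.5; a hemizygous male X shows no BAF near 0.5 and an LRR depressed by
about one unit of log2.

## A composition sensitivity worth knowing about

Within-sample quantile normalization couples the two channels through
their *rank* distributions.  When the intensity distribution is sharply
trimodal — as in the synthetic data here, where every marker shares the
same canonical centroids — a sample with more AA than BB calls (or vice
versa) has mismatched block boundaries in the two sorted channels, and
values falling in the boundary gap are dragged toward the neighbouring
block.  The per-sample mean BAF at heterozygous calls therefore deviates
from 0.5 roughly linearly in the sample's `n_AA - n_BB` imbalance (about
4e-4 per marker of imbalance at 2,000 markers); the deviation averages out
across samples, and the pooled mean stays within ~0.01 of 0.5.  Real
arrays, with marker-specific cluster positions and continuous intensity
spreads, show the effect only for samples with genuinely unusual genome
composition.

# Quality control and sex inference

Failed arrays show up as aberrant intensity distributions, excess missing
calls, excess heterozygosity, or combinations of these.  `sample_qc()`
tabulates all of them; heterozygosity thresholds are applied to raw counts
(matching per-array totals), with rates also reported.  `flag_samples()`
applies global or subgroup-specific thresholds (e.g. per plate) and is
monotone by construction: relaxing a threshold can never fail a passing
sample.

Sex is inferred from two signals: males are hemizygous on X, so their
X-heterozygosity is near zero (threshold 0.1 by default, comfortably
between male error rates and female autosome-like rates), and they carry
Y-marker signal where the array has Y probes.  The Y intensity threshold
defaults to 0.275 — midway between the simulated female background
(R about 0.05) and the hemizygous male signal (R about 0.5 on an array
normalized to R = 1 for diploid calls).  Pseudoautosomal markers (flagged
"XY" in the manifest) are excluded from the X rate.  Discordance between
inferred and recorded sex is a standard screen for swaps and
contamination.

# Population-genetic summaries

IBS distance is one minus the proportion of alleles shared identical by
state, averaged over jointly non-missing markers: per marker the shared
fraction is `(2 - |d_i - d_j|) / 2`.  Pairs with fewer than `min_overlap`
joint markers are reported missing rather than estimated from noise.
Hierarchical clustering of the distance matrix uses average linkage by
default (configurable); the leaf order places related samples adjacently
for heatmap display.

PCA mean-imputes missing calls per marker, centers, and optionally scales
by the binomial dosage standard deviation `sqrt(2p(1-p))`; both modes are
exposed because practice varies.  Signs follow a deterministic rule (the
largest-magnitude loading of each component is positive) so projections
are reproducible across runs and marker orderings.

Mendelian checks enumerate, per marker, whether the offspring dosage is
attainable from one allele per parent; with a single observed parent only
the shared-allele rule applies (opposite homozygotes are inconsistent);
male-offspring X markers are tested hemizygously against the mother.
Markers with a missing offspring call are not tested.

# Merging and recoding

Datasets are joined on marker name, with chromosome/position agreement
verified (name-only joins are fragile; position-only joins break on
multi-mapping manifests).  The second dataset's allele encoding is
reconciled to the first's: identical encodings pass through, swapped A/B
labels flip dosages, reverse-strand encodings are complemented first.
A/T and C/G SNPs are strand-ambiguous — a flip is indistinguishable from a
swap — so they are kept when the encodings already agree and dropped on any
conflict.  The merge aborts if more than half the shared markers are
irreconcilable, which almost always means incompatible manifests.
`recode_by_parents()` re-expresses calls as dosage of the second parental
line's allele, keeping only markers where the parents are opposite
homozygotes.

# The haplotype-mosaic HMM

The decoder reconstructs a chromosome as segments copied from a panel of
H reference haplotypes along a genetic map.  Hidden states are haplotypes
(haploid mode) or unordered pairs (diploid mode, `H(H+1)/2` states,
transitions factoring as two independent chromosomes).  Between markers
separated by `d` cM the ancestry is retained with probability
`exp(-jump_rate * d)`; otherwise the new haplotype is uniform over the
panel, the usual copying-process construction whose infinite-distance
limit is the uniform distribution.  Emissions flip each allele
independently with probability `error_rate`; missing observations are
uninformative.  Decoding is by log-space Viterbi with ties broken toward
the lowest-index state, and `posterior()` provides scaled
forward–backward marginals.  Observations are genotype dosages — the HMM
deliberately does not emit on intensities, so it works on any dataset with
calls.

# The synthetic-data generator

Every stage of the package is testable without downloads because the
generator produces datasets with known ground truth, emulating the
standard intensity model: per call, polar coordinates are drawn around the
canonical centroids (theta 0.05/0.5/0.95, R = 1) with Gaussian noise
(sigma 0.03 by default, a clean modern array) and inverted *exactly* into
channel intensities, so at zero noise `theta_r()` recovers the simulated
coordinates bit-for-bit and `R = x + y = 1` exactly at every diploid call.
Population structure is logit-normal drift of ancestral frequencies
(ancestral p uniform on 0.05–0.95); the `divergence` parameter is on the
allele-frequency scale — frequencies drift with logit-sd `4 * divergence`,
so intermediate frequencies are displaced by about `divergence` — with 0.3
corresponding to strong, subspecies-level differentiation.  Males are
hemizygous on X and Y (dosage 0 or 2, R scaled by 0.5); female Y markers
and missing calls emit background intensity.  Contamination mixes two
samples' channel intensities at a stated fraction, which displaces
homozygote BAF away from 0 and 1 — the classic contamination signature.
Trios inherit one allele per parent per marker, with an option to plant a
known number of Mendelian errors at known markers.

What the generator does *not* emulate: linkage disequilibrium, coalescent
genealogy, marker-specific cluster positions, plate/batch effects, or
probe failure modes.  Tests passing on this data therefore demonstrate the
correctness of the algorithms under the stated model, not robustness to
every artifact of real arrays.

# Numerical and design choices

* Problem sizes in the test suite are desk-scale by design — a few
  thousand markers and tens of samples reproduce every claimed property;
  the calibration checks use 2,000 autosomal markers, 20 study samples and
  50 reference samples.
* All generators take a mandatory seed and are bit-reproducible under it.
* Ties in quantile-normalization ranks use average rank; ties in Viterbi
  break toward the lowest-index state; the PCA sign rule is as above.
* Degenerate inputs are mapped to missing rather than errors wherever a
  per-marker failure should not poison a dataset: markers without usable
  clusters get missing BAF/LRR, `R <= 0` gives missing LRR,
  `x = y = 0` gives missing theta.
* `write_plink()` sets A1 to the B allele so PLINK's count-of-A1 equals
  the internal B dosage; this is deliberately documented in the function
  help because PLINK users often assume A1 is the minor allele.
* FinalReport writing supports gzip compression; ZIP archives are
  supported on the read side (the first entry is used unless a member is
  named).
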