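---
title: "peachscan: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peachscan: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peachscan)
```

`peachscan` bundles the computational stages of a wild-peach genomics
workflow — genome-size survey, bulked-segregant trait mapping, a
two-group selective-sweep scan, gene-origin assignment, pan-genome
family classification and the 4DTv divergence statistic — together with
seeded simulators that generate statistically realistic inputs for each
stage.  This vignette records the underlying models, what every tunable
parameter means and why its default was chosen, and the limits of what
the simulators can demonstrate.

## Genome size from a k-mer histogram

For a histogram `count[d]` of distinct k-mers (default k = 17) observed
at depth *d*, the estimator is

> G = (Σ_d d · count[d]) / d_peak,

where `d_peak = argmax_d count[d]` over `d >= min_depth`, ties broken
toward the smaller depth for determinism.  Sequencing errors produce a
large spike of low-depth k-mers; rather than detecting the valley
between the error and the genomic peak we use a fixed cutoff
(`min_depth = 4`, configurable), which is deterministic and matches
common survey practice.  The same cutoff is applied to the numerator:
k-mers below `min_depth` are putative errors, and counting their
instances would inflate the estimate (with an error spike containing
half as many instances as the genome itself, the estimate would be 50%
high).

A caveat worth knowing: for an integer mean depth λ the Poisson
distribution has tied modes at λ−1 and λ, so the empirical peak of an
error-free histogram simulated at depth 40 is 39 or 40 with roughly
equal probability, and a single estimate is either ~0.03% or ~2.6% from
the truth.  Averaging a handful of replicate histograms removes the
coin flip; the package's recovery checks score the mean over seeded
replicates.  Heterozygosity and repeat modelling (GenomeScope-style
mixture fits) are out of scope.

## Bulked segregant analysis (Δ SNP index)

The design is a BC₁ population from a resistant donor crossed to a
susceptible recurrent parent, with two phenotype pools of 20 seedlings
sequenced as bulks.  Informative markers are sites where the parents
are homozygous for different alleles.  The SNP index of a pool is the
fraction of its reads carrying the **donor** allele; the QTL-seq-style
filter removes loci whose index is below 0.3 or above 0.7 *in both
pools* (such loci are jointly near-fixed and carry no segregation
signal).  We read the filter this way because the alternative parse —
remove a locus if either pool leaves [0.3, 0.7] — would discard exactly
the loci that carry the mapping signal (a causal locus has
index_res = 0.5, index_sus = 0.0); the alternative remains available as
`filter_by_index(rule = "either")`.

Referencing the index to the donor allele fixes the sign convention:
Δ = index_res − index_sus is +0.5 in expectation at a dominant
resistance locus (the resistant pool is entirely heterozygous there,
the susceptible pool entirely recurrent-homozygous) and decays toward 0
with recombination distance.  Window means use a 1-Mb window sliding by
100 kb — window sizes for this stage are a free choice, and 1 Mb
matches the scale at which a 20+20 pool design can localize a locus.
The candidate region is the contiguous run of windows whose |mean Δ|
exceeds the genome-wide 95th percentile, anchored at the most extreme
window (ties toward the smaller coordinate); we do not implement
simulation-based confidence envelopes, since thresholding by the
genome-wide quantile is sufficient for a single-locus design.

## The selective-sweep scan

The scan takes a biallelic genotype matrix (dosages 0/1/2, missing
allowed) and a two-group assignment — by default emulating 10
high-altitude vs 27 low-altitude accessions.  Per site, with allele
sample size n (twice the genotyped samples) and alt frequency p:

- unbiased heterozygosity: 2p(1−p)·n/(n−1), summed over a window and
  divided by the full window length to give per-bp π.  The full-length
  denominator is the standard convention when invariant sites are not
  in the VCF; it makes π comparable across equally sized windows but
  not an absolute diversity estimate.
- Hudson's F_ST: per-site numerator
  (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and denominator
  p₁(1−p₂) + p₂(1−p₁), combined per window as a ratio of sums.  The
  Hudson estimator was chosen because it is the least sample-size
  sensitive of the common two-population estimators; no estimator is
  dictated by the analysis itself.
- Tajima's D per group, from θ̂_π (count units) and θ̂_W = S/a₁ with
  the standard normalizing constants.  The variance formula assumes a
  fixed n, so within a window the modal allele sample size is used and
  sites whose n deviates from it by more than 20% (configurable,
  `n_dev`) are excluded from D; windows with no segregating site have
  undefined D and are excluded from quantile computations.

Windows are 50 kb sliding by 10 kb, laid from position 1 while they fit
inside the chromosome.  Selection takes the extreme 5% tail of each
statistic over defined windows: *lowest* π_high/π_low (diversity
reduction in the high group is the sweep signal; direction
configurable), *highest* F_ST, and *most negative* D_high − D_low.  A
difference rather than a ratio of the two groups' D is used because
ratios of signed quantities are unstable around zero.  The three
criteria combine by intersection by default (`union` and `any-two`
available); empirical quantiles include ties, so marginally more than
5% of windows can pass a single criterion.  Selected windows are merged
(overlapping or abutting) and annotated with genes overlapping ≥ 1 bp.

## Gene origin and gene families

For a putative hybrid's genes, each query is aligned to every candidate
ortholog of every donor species with Smith–Waterman local alignment
(affine gaps; BLASTN-like defaults match +1, mismatch −2, gap open −5,
gap extend −2, a gap of length L costing 5 + 2L; `N` matches nothing).
The per-species score is the best over that species' sequences and the
gene is assigned to the species attaining the strict maximum, subject
to an optional minimum score and winning margin; exact ties are
"ambiguous" rather than broken arbitrarily.  Ortholog inference itself
(clustering, synteny) is input, not computed.

Family presence/absence classification uses the standard pan-genome
semantics: a family present in every species is *core*, in exactly one
*specific*, otherwise *dispensable*.

## 4DTv

For a codon-aligned pair, a third position is a usable
fourfold-degenerate site iff **both** codons are fourfold degenerate
(first two bases in CT, GT, TC, CC, AC, GC, CG, GG), their first two
positions are identical, and neither codon contains a gap or ambiguity
code — the conservative standard; codons violating it are skipped
entirely.  The statistic is transversional differences at those sites
divided by the number of sites, as a raw proportion without
multiple-substitution correction (corrections such as HKY exist in the
literature but are not part of the definition used here).  Block values
pool sums over all gene pairs of a syntenic block — Σtv/Σsites, not the
mean of per-pair ratios, so short pairs are weighted by their site
counts.

## What the simulators emulate — and what they do not

All generators are deterministic given a seed and write truth sidecars.

**BC₁ pools** (`simulate_bc1`): 200 offspring over a 25-Mb chromosome
with 500 markers, causal locus at 6.5 Mb, 20+20 pools, pooled depth 50.
Gametes follow a Haldane map (no crossover interference), the simplest
defensible meiosis model for Δ decay.  The recombination rate default
is 1e-7 Morgans/bp (10 cM/Mb), making the chromosome ~2.5 Morgans so
that markers distal to the locus are effectively unlinked (E[Δ] ≈ 0),
which the BC₁ mapping design assumes; at substantially lower map
lengths the whole chromosome stays in partial linkage with the locus
and no window-based method can localize it sharply.  Pool read counts
are Binomial(depth, pool allele frequency); no read-level errors,
mapping artifacts or segregation distortion are modelled, so the
recovery rates measured here are upper bounds for real data.

**Sweep matrices** (`simulate_sweep`): background frequencies are
Beta(0.5, 0.5) shared between groups; genotypes Binomial(2, p) per
sample (Hardy–Weinberg, no linkage disequilibrium between sites).
SNP density defaults to ~5,600/Mb (56,000 sites over 10 Mb), the
genome-wide density of the high-quality SNP set this scan design is
built for; at several-fold sparser densities the per-window Tajima's D
of a 10-sample group becomes too noisy for the intersection criterion.
Inside the sweep interval the high group's frequency is warped toward
the nearer boundary (p^γ below 0.5, 1−(1−p)^γ above; γ = 8 default,
γ = 1 the null), which jointly produces the three selection signals
without coalescent machinery.  Because sites are exchangeable there is
no background LD, no allele-frequency correlation between neighboring
windows beyond window overlap, and no demography; null false-positive
rates in real data will be higher.

**k-mer histograms** (`simulate_kmer_histogram`): single-copy genomes
only — every true k-mer is Poisson(depth); the error peak is a
singleton spike at depth 1.  Repeats and heterozygosity (shoulder
peaks) are not modelled.

**Codon pairs / origin fixtures**: third positions mutate independently
with fixed transversion/transition probabilities; origin fixtures
radiate each gene from an ancestral sequence with per-species
divergence rates and plant a uniformly drawn true donor.  Indels,
selection on codon usage and rate heterogeneity are not modelled.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive throughout; BED converts at the
  boundary.
- Quality filtering masks individual calls (depth < 5 or GQ < 5 becomes
  missing) before the per-site missingness rule (< 0.2), because a
  per-site missingness threshold is only meaningful after per-sample
  masking; missing quality fields count as failing.  The filter is
  idempotent.
- Multi-allelic VCF records are skipped by default (all downstream
  statistics assume biallelic sites); `multiallelic = "split"` emits
  one record per alternate allele.
- Zero-depth pools, windows without SNPs, windows without segregating
  sites, and histograms with no k-mers above `min_depth` all yield
  explicit undefined values or errors, never silent zeros (the one
  deliberate exception: π of an empty window is 0, since absent
  positions contribute no diversity).
- Peak/tie rules (k-mer peak, BSA peak window, origin ties) are all
  deterministic and documented above.

## Problem sizes used in the checks

The test suite validates the window statistics against brute-force
oracles on 1,000 random windows (allele sample sizes 8, 20 and 54, up
to 200 sites), runs 100 seeded BC₁ replicates at the full study design
and 50 seeded sweep replicates (plus 10 nulls) at the 10-vs-27 design,
and checks the aligner against a quadratic-space dynamic-programming
oracle on 200 random pairs.  These sizes make the whole suite run in a
few minutes on a single core while keeping the Monte-Carlo error of the
measured rates well below the margins being asserted.

## Known limitations

- The sweep scan reports fixed-grid window statistics; it does not
  estimate sweep boundaries or selection coefficients.
- Tajima's D with heavy, unevenly distributed missingness discards
  sites (the modal-n rule) rather than re-deriving variance constants
  per site.
- The local aligner is exact but quadratic; for genome-scale origin
  scans a seeded heuristic aligner would be substituted at the same
  interface.
- Recovery rates quoted for the simulators transfer to real data only
  to the extent the generative assumptions above hold; they are design
  checks, not benchmarks.
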