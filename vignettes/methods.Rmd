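---
title: "Methods: models, conventions and design choices in ptilomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in ptilomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptilomap)
```

# Scope

ptilomap implements the inference chain for fine-mapping two dominant
feathered-leg loci in the chicken: pooled-array RAF scans, pool-seq
ZF~ST~ window scans, two-point backcross linkage, consensus-based IBD
region detection with exclusion filtering of candidate causal variants,
conserved-element annotation, and two-locus genotype–phenotype
statistics. It consumes standard text formats (a GT-only VCF subset
with symbolic `<DEL>` records, BED3, tab-separated tables) and ships
simulators that generate all of them, so the entire pipeline is
exercised and validated on synthetic data. Read alignment, variant
calling, transcription-factor binding-site prediction and real-genome
reanalysis are out of scope: the package starts from variant tables.

# Coordinate and genotype conventions

All internal coordinates are 1-based and fully inclusive (VCF
convention), so a region's length is `end − start + 1`; BED input is
converted at the boundary (`start + 1`). This convention is the only
one under which the published landmark intervals reproduce their
printed sizes exactly — e.g. the 472-bp conserved-element interval and
the 17.7-kb (17,668 bp) deletion — and it is used for every interval in
the package. Chromosome names are compared as exact strings; nothing
strips or adds a `"chr"` prefix silently.

Genotypes are unphased alt-allele dosages 0/1/2 with `NA` for missing;
`"|"` separators in VCF input are treated as `"/"`, and multi-allelic
records are rejected rather than silently split. Missing genotypes are
excluded site-wise from all downstream counts.

# The cross simulator

`simulate_cross()` draws meioses under Haldane's model: the crossover
count per chromosome is Poisson(map length in Morgans) and crossover
positions are uniform on the cM scale, with no interference. Founders
are fixed for different alleles at every marker (the situation in the
mapped cross, where both parental breeds were purebred), so each F1
gamete is a mosaic of founder segments and every backcross offspring is
one informative meiosis.

Phenotypes come from a thresholded liability: each causal locus with
alt dosage $g$ contributes $a\,g + d\,[g{=}1]$ score units, plus
Normal(0, $\sigma$) residual noise, and the ordinal category is the
number of cut-points below the liability. The default backcross
parameterisation used throughout the tests ($a = d = 0.5$,
$\sigma = 0.25$, cuts at 0.161 and 0.724) was chosen once, before any
scan experiments, to reproduce the three-class phenotype structure of
the mapped backcross: roughly 37% clean, 20% intermediate and 43%
feathered offspring, with intermediates arising from *both* genotype
classes — carriers with low liability and non-carriers with high
residuals. This mirrors the key nuisance feature of the real cross
(intermediate birds are genetically mixed and are therefore excluded
from pools and from linkage scoring). The residual term stands in for
the minor polygenic background suggested by wild-type intermediates; it
is not a fitted quantity.

What the generator does **not** emulate: genotyping error on the array,
unequal DNA contribution to pools, segregation distortion, sex
linkage, and interference. Passing recovery tests therefore show the
statistics behave correctly under the stated model, not that they are
robust to every artefact of real array or sequencing data.

# Pooled scans

`compute_raf()` is exactly `X/(X+Y)`; zero-intensity sites are flagged
missing, not errors. Pool intensities are simulated as
`gain × allele count + Normal(0, noise_sd)` clamped at zero, i.e. equal
DNA contribution per pooled individual. In the noise-free backcross
design the affected pool is all-heterozygous and the unaffected pool
homozygous, so the maximum achievable `absRAFdif` is exactly 0.5; this
is both a sanity invariant and the quantity recomputed by
`scripts/acceptance.R`.

Peak calling uses the min–max rule: the peak interval spans the first
to the last SNP whose value strictly exceeds the threshold (default
0.35) on the requested chromosome. No smoothing or box-drawing
heuristic is applied.

Per-site F~ST~ is the plain heterozygosity ratio
$(H_T - H_S)/H_T$ on pool read frequencies, without pool-size or
coverage bias correction: downstream use is rank-based (ZF~ST~), which
is insensitive to monotone changes of the estimator, and the filter
thresholds (per-pool depth in `[min_depth, 3 × mean depth]`, minor
allele count ≥ 2) are configurable. Windows are anchored at position 1,
advance by `step`, and only full-size windows are emitted; the window
value is the unweighted mean of contained sites, empty windows carry
`NA` so the tiling stays complete, and Z-normalisation uses the sample
(n−1) SD over all non-missing windows genome-wide. These are fixed
conventions chosen to make results exactly testable; the method they
implement does not depend on them.

# Two-point linkage

For a dominant trait in a backcross, carrier status is read directly
from the phenotype (intermediates excluded), each offspring is an
informative meiosis, and the recombination fraction estimate is
$\hat\theta = \min(r/n, 1/2)$ with
$\mathrm{LOD} = (n-r)\log_{10} 2(1-\hat\theta) + r\log_{10} 2\hat\theta$.
Phase is chosen per marker to minimise recombinants (the two-point
convention; with founder-fixed markers the minimising phase is the true
one). The $r=0$ limit is $n \log_{10} 2$ and $\hat\theta = 1/2$ gives
LOD 0; negative LOD values cannot occur at the MLE. Interval narrowing
localises each recombinant's crossover between its last
phase-concordant and first discordant marker; the candidate interval is
the maximal marker run concordant with every recombinant, extended to
the prior interval's edge on any side with no discordant marker.
Recombinants whose concordance pattern switches more than once (an
apparent double crossover, more often a genotyping error) are flagged
and excluded with a warning rather than allowed to corrupt the
interval.

# IBD detection and exclusion filtering

IBD sharing is detected from unphased genotypes by homozygous-core
consensus: a site is *defining* when every genotyped core sample is
homozygous for one common allele and every genotyped carrier sample
holds at least one copy of it; any other configuration is a *break*.
Maximal runs of defining sites (with at least `min_sites` of them) are
reported, each spanning its first to last defining site — the same way
published IBD region bounds come from the outermost shared variants.
This deliberately avoids phasing, imputation and probabilistic IBD
models: the intended use case is breed panels largely homozygous for a
swept haplotype, with occasional heterozygous carrier breeds handled by
the carrier-compatibility rule. Two scan modes follow from the panel
annotation alone: "all cases are core" (the chromosome-15 situation)
and "explicit core/carrier/non-carrier classes" (the chromosome-13
situation, where some feathered-leg breeds do not carry the haplotype);
there is no automatic best-subset search, which would be combinatorial
and unjustified by genotype data alone.

`max_mismatch` (default 0) converts up to that many break sites per
region into skips, for panels with genotyping errors; regions are then
grown greedily left-to-right, absorbing breaks while the budget lasts.
Missing genotypes never break a region (the sample is skipped at that
site).

Exclusion filtering keeps variants whose span intersects the IBD
interval, with all genotyped cores homozygous alt, all genotyped
carriers carrying the alt, and zero alt alleles among genotyped
controls — provided at least 90% of controls are genotyped at the site
(`max_missing = 0.1`). The control-missingness policy is a declared
default: the correct treatment of ungenotyped controls is not derivable
from first principles, and the parameter is exposed. Deletions
participate exactly like SNVs through their genotype columns; their bp
span is additionally used for interval containment and annotation.

# The panel simulator

`simulate_panel()` models descent of a causal haplotype: each case's
shared segment is anchored at the causal site and extends on each side
by an independent Exponential(rate = G per Morgan) arm, converted to bp
through a linear genetic map (default 5 cM/Mb, a microchromosome-like
rate). Core cases are autozygous for the founder haplotype inside their
segment; carriers hold one founder copy; outside segments and in
controls, genotypes are Hardy–Weinberg draws at per-variant frequencies
uniform on [0.05, 0.95]. The causal alt allele appears in no control.
`G` defaults to 200 — the trait has been under fancier selection for at
least hundreds of generations, and at 5 cM/Mb this yields realized IBD
intersections of a few tens of kb across 8 cases, the length scale of
the published 30-kb and 53-kb regions. When several causal variants are
planted (e.g. an SNV and a 17.7-kb deletion), each arm is stretched to
cover the farthest causal edge so that every case carries all of them;
this slightly lengthens the realized IBD interval and is the price of
guaranteeing the genotype invariants. The exponential-arms construction
matches expected IBD segment-length theory without a forward
population simulation; it does not model allele-frequency drift,
mutation on the shared haplotype, or relatedness among controls.

# Validation experiments and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive interval enumeration for the IBD scan (panels up to 20 sites
× 8 samples), the explicit binomial likelihood ratio for all LOD values
with n ≤ 50, per-base set intersection for interval overlap, exhaustive
alignment enumeration for global alignment scores (sequences up to
length 8), and direct arithmetic for F~ST~ and chi-square. Recovery
experiments run the full pipeline on simulated data: 100 seeded
backcross array scans (100 offspring, 50 markers on a 13-Mb
chromosome) for absRAFdif peak recovery, and 25 seeded panels
(8 cores, 40 controls, 0.6 background variants per kb) for IBD boundary
recovery, whose mean boundary error is required to stay under twice the
mean marker spacing.

The ZF~ST~ window-recovery experiment needs one deliberate design
choice. In a backcross the affected pool is all-heterozygous, so
per-site F~ST~ is capped at 1/3, and with a realistic map the decay of
F~ST~ across a 50-kb window at desk-scale sample sizes is far smaller
than its sampling noise — single-SNP windows adjacent to the causal one
then win the argmax essentially at random, and window-level
localisation is unattainable (the real experiment this emulates also
only localised the signal to a multi-Mb region at this stage). The
recovery experiment therefore uses a genetically compressed scan
chromosome — 201 sites 10 kb apart with 3 cM between adjacent sites,
400 offspring, 200× pools — so that the linkage-decay scale matches the
50-kb window scale while everything else (the F~ST~ estimator, window
logic, Z-normalisation) is exercised unchanged. This is a statement
about the geometry of the experiment, not a tuning of the statistic.

# Phenotype statistics

Ordinal feathering scores (0–4 at hatch, 0–9 adult) are treated as
numeric for means, SDs and t-tests — a deliberate fidelity-over-purity
choice matching how such scores are conventionally analysed; ordinal
regression is out of scope. Pairwise tests default to the two-sided
pooled-variance Student's t-test, with Welch's test and a Bonferroni
factor available by flag (no correction is applied by default across
the 36 possible combination contrasts). Adjusted digit length is
`digit4/shank` per individual. Sexes are pooled; the simulator has no
sex effect. The segregation test is the Pearson goodness-of-fit
chi-square against a stated ratio, with `df = classes − 1` and no
continuity correction.

# Known limitations

- The IBD scanner assumes the causal haplotype is old and swept; it
  will fragment or miss regions in panels with high genotyping error
  unless `max_mismatch` is raised, and it cannot detect sharing among
  carriers that are all heterozygous (no cores).
- The F~ST~ estimator carries no finite-pool or coverage correction;
  absolute window values are therefore not comparable across studies,
  only ranks within a scan.
- The alignment identity denominator includes gap columns; published
  identity percentages computed under other conventions (or other gap
  penalties) are not directly comparable.
- `sliding_windows()` emits full windows only; a trailing partial
  window at a chromosome end is dropped.
- The simulators are generative models for validation, not fitted to
  any dataset; their defaults define plausible study conditions rather
  than estimates.
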