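---
title: "Methods: windowed genome scans for balancing selection and divergent sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed genome scans for balancing selection and divergent sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Ancient balanced polymorphisms leave two complementary footprints in a set
of diverged populations. Where balancing selection has maintained two deep
haplogroups at intermediate frequency in *every* population, windows show
jointly elevated nucleotide diversity (high π, positive Tajima's D) but no
excess differentiation. Where the same ancestral haplogroups were instead
*sorted* — fixed alternately in different descendant lineages — windows
show jointly elevated relative (F~ST~) and absolute (d~XY~) divergence.
`popgenscan` implements the full windowed-scan machinery needed to detect
and test both footprints in a highly inbreeding plant system with four
geographic groups, together with a coalescent synthetic-data generator
that makes every stage testable without access to the original
re-sequencing data.

# Statistics

All statistics are computed in non-overlapping windows (20 kb by default)
and use callable-site denominators so monomorphic sites count:

* π: per site, `sum over variable sites of 2 i (n - i) / (n (n - 1))`
  divided by the number of callable sites, with `n` the per-site
  non-missing haploid count and `i` the alternate count.
* θ~W~ = S / (a₁ · callable sites); Tajima's D uses the classic constants
  with `n` taken as the window-median per-site sample size (per-site `n`
  varies with missingness; the source procedure is silent, so the median
  is our documented choice).
* Fay & Wu's H = θ~π~ − θ~H~ (unnormalized), with sites polarized against
  a single outgroup sequence; sites with no outgroup allele are dropped.
* Weir–Cockerham weighted F~ST~ is a **ratio of averages**: per-site
  variance components a and a+b+c are summed over sites before dividing.
  The mean of per-site ratios is a different (worse) estimator, and a
  regression test asserts the two disagree on crafted input. Haploidized
  genotypes are treated as fully homozygous diploids, which zeroes the
  within-individual component c.
* d~XY~ = mean over callable sites of p₁(1−p₂) + p₂(1−p₁);
  d~a~ = d~XY~ − (π₁+π₂)/2; RND = d~XY~ divided by the mean divergence of
  the two populations to the outgroup over the same site set (the site
  matching is our choice; the source is silent).

Windows are eligible for basic statistics at ≥ 5,000 callable sites, for
segregating-site statistics at ≥ 20 SNPs in addition, and for outgroup
statistics at ≥ 2,000 outgroup-aligned bases.

# Outlier screen

Per-window statistics are standardized to Z scores separately per group
(π) or per pair (F~ST~); windows with Z ≥ 2 (inclusive) are islands.
We use the population (denominator n) standard deviation; a config switch
(`sd_type`) selects n−1, since the convention is not fixed by the source.
The F~ST~ standardization is a plain Z-transform (x − mean)/sd — the
"(F~ST~ × F~ST~′)/std" form sometimes printed is read as a typo for
subtraction, because the quantity is called Z-transformed and thresholded
at Z ≥ 2. π-islands shared by **all** groups are intersected and merged
into candidate balancing-selection (BLS) regions when separated by less
than 1.5 Mb (strictly; a gap of exactly 1.5 Mb does not merge). Detected
BLS regions are excluded (any overlap excludes a window) before the
F~ST~ screen, because long-term balancing selection suppresses
differentiation and would distort the F~ST~ mean and sd.

Island-versus-background contrasts use a randomization test: the null
redraws |islands| windows without replacement 100,000 times (reduced in
unit tests), two-sided P = (#{|null| ≥ |obs|}+1)/(n+1), so the smallest
reportable value at the full count is just under 10⁻⁵. Comparisons against
coalescent nulls use a two-sided Mann–Whitney U with tie-corrected normal
approximation, switching to exact enumeration when both samples have ≤ 8
observations. ρ/π comparisons (recombination scaled by diversity to cancel
local N~e~) report class means, a one-way F across region classes, and
Bonferroni-adjusted randomization P values; an `lm`-based test reports the
island effect controlling for ρ/π and gene density jointly.

# The synthetic-data generator

The generator is a structured backward-in-time coalescent written in C++:
populations with piecewise-constant diploid sizes, scheduled merges
(splits in forward time) and a constant backward migration matrix.
Mutations follow infinite sites at rate μ per site per generation with
μ = (7 × 10⁻⁹ /site/year) × (2 years/generation) = 1.4 × 10⁻⁸ by default.
Design choices:

* **Windows are independent loci.** The screen's own null treats 20-kb
  segments as independent, so inter-window linkage is not modelled.
* **Within-window recombination** uses a block-independence
  approximation: the window is cut into k = max(1, round(4 · Morgans ·
  N~e~)) equal non-recombining blocks (N~e~ from the root population),
  capped at 64 — beyond that the inter-window variance reduction that the
  approximation exists to reproduce has saturated. The qualitative
  property (variance of per-window π falls as the recombination rate
  rises from 0 to 250 cM/Mb; the mean is unchanged) is what downstream
  analyses consume, and it is under test.
* **Exponential growth epochs** are discretized into 32 log-linear
  piecewise-constant steps before simulation.
* **Signal injection by grafting.** Balanced and sorted regions are
  modelled by their coalescent signature, not by selection dynamics: the
  sample is partitioned into haplogroups A/B at the spec's per-population
  frequencies, each haplogroup coalesces under the demography conditioned
  on finishing before the graft time (rejection sampling), and the two
  subtrees are joined at the haplogroup TMRCA (default 5 × 10⁵
  generations ≈ 1 My at 2 y/generation, matching the depth of the most
  divergent island haplotypes). Stem mutations become sites fixed between
  haplogroups. Signal windows are single non-recombining blocks: grafting
  and recombination across the balanced site are not jointly modelled.
* **Outgroup.** A single outgroup lineage joins the root at 2.5 × 10⁶
  generations by default (no estimate of the true outgroup divergence is
  available; the value only needs to exceed every ingroup TMRCA). Under infinite
  sites the outgroup carries the ancestral allele at ingroup-segregating
  sites, so folded spectra equal folded unfolded spectra by construction
  — a property test, not an accident.
* **Inbreeding.** Each diploid is fully homozygous with probability 0.98
  (the species is described only as "largely inbreeding"; 0.98 is our
  free parameter, chosen once), else keeps two distinct haplotypes.
* **Depth/error layer.** Depth ~ Poisson(mean), heterozygote allelic
  depths ~ Binomial(depth, 0.5), per-read error flips support; genotypes
  are re-called from reads, which generates realistic missingness and
  false heterozygotes for the QC layer to remove. Per-window callable
  counts are drawn from the binomial tail probability that ≥ 50% of
  samples have coverage — an emulation, not a per-site bookkeeping, and
  documented as such.

## Default study conditions

The default four-population model is the best-fit
isolation-with-migration parameterization estimated for this four-group
system: topology (WES,(COL,(UTA,NOR))) with splits at 89,500 / 35,000 /
15,000 generations (179 / 70 / 30 KYA), ancestral sizes 24,000 / 36,000 /
39,000, post-split sizes 19,000 / 100,000 / 110,000 / 11,000, and weak
symmetric migration (10⁻⁶ per generation, inside the estimated
6.8 × 10⁻¹⁰–2.0 × 10⁻⁵ range). The recent-expansion epochs (12 and
7.7 KYA) are omitted because their terminal sizes are not established;
post-split sizes are held constant instead, which keeps genome-wide
diversity and differentiation at realistic levels for the system
(e.g. simulated F~ST~(WES, NOR) ≈ 0.6 versus 0.56 observed).

# What passing tests do and do not show

The generator emulates coalescent variation, inbreeding and a read-depth
layer. It does not emulate alignment or mapping artifacts, paralogy,
indels/multi-allelic sites, mutation-rate heterogeneity along the genome,
linked selection, or FASTQ-level noise — so green tests certify the
statistics and the scan logic, not robustness to upstream calling errors
in real data.

Two statistical facts surfaced by testing are worth recording. First,
Tajima's D has a small negative finite-sample expectation (≈ −0.1 at
n = 20 haplotypes), so its neutral mean is checked against an absolute
band (|mean| < 0.15) rather than against zero. Second, a *fully neutral*
four-group genome of 5,000 windows is **not** expected to be free of
shared π-islands under this demography: a window has one genealogy
spanning all groups, and with recent splits and large post-split sizes
most coalescence happens in shared ancestral populations, which
correlates the per-group Z-π tails (joint flag rate ≈ 5 × 10⁻⁵ per window
against 2.7 × 10⁻⁷ under independence; ≈ 0.25 expected shared windows per
neutral genome, so ≈ 20% of neutral genomes show at least one). The
shared-island screen is therefore an enrichment device, not a
false-positive-free detector, and the corresponding zero-false-positive
acceptance check fails honestly at these conditions.

# Problem sizes and numerical choices

Test and example runs use 1,000 neutral loci for moment-recovery
experiments (Monte-Carlo SE ≈ 1% of the estimate), a 5,000-window genome
with three balanced (25 windows each) and two sorted (15 windows) regions
for the end-to-end scan, 20 replicate neutral genomes for the
false-positive rate, and reduced permutation counts (199–4,999) for
calibration suites; the full 100,000-segment, 100,000-permutation
configuration is available through the same interfaces. Randomization and
Mantel P values use the (count+1)/(n+1) convention so zero is never
reported. Hypergeometric SFS downsampling discards sites below the
projection target in any population and ledgers the count; an exact 50%
folded tie is counted once in the top folded class. Hill–Weir decay fits
run bounded Levenberg–Marquardt (ρ ≥ 0) and report a boundary estimate
rather than failing when the data are flat.
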