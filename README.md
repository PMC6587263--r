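# popgenscan

Windowed population-genomic scans for regions shaped by long-term
balancing selection and by divergent sorting of ancestral polymorphisms,
with a built-in coalescent synthetic-data generator.

## The problem

In a set of diverged populations, ancient balanced polymorphisms leave two
signatures. Haplogroups maintained at intermediate frequency in *all*
populations produce windows of jointly elevated diversity (high π,
positive Tajima's D) without elevated differentiation. Haplogroups fixed
alternately between populations ("sorted") produce windows of jointly
elevated F<sub>ST</sub> and d<sub>XY</sub>. `popgenscan` provides the
whole analysis chain used to find and test both patterns in multi-sample
SNP data from a highly inbreeding plant:

* **QC** — genotype masking (hom < 2 reads; het < 20 reads or reference
  read fraction outside [0.25, 0.75]), site filters (≥ 50% missing, mean
  depth > 20, multi-allelic, > 15% heterozygous, indel), sample filters
  (> 60% missing), and TP/FHET/FHOM/MISS concordance reports.
* **Window statistics** — π, θ<sub>W</sub>, S, Tajima's D, Fay & Wu's H
  (outgroup-polarized), with 5,000-callable-site / 20-SNP / 2,000-outgroup-base
  eligibility rules; SFS construction with hypergeometric downsampling to
  fixed projection sizes (39/78/63/52 by default).
* **Divergence** — Weir–Cockerham weighted F<sub>ST</sub> as a ratio of
  averaged variance components, d<sub>XY</sub>, d<sub>a</sub> =
  d<sub>XY</sub> − (π₁+π₂)/2, and RND (outgroup-normalized d<sub>XY</sub>).
* **Outlier screen** — per-group/per-pair Z-transforms, island calling at
  Z ≥ 2, intersection of π-islands across all groups, merging into
  regions at gaps < 1.5 Mb, exclusion masks, randomization tests
  ((count+1)/(n+1), two-sided), ρ/π comparisons with one-way F and
  Bonferroni correction, and covariate-adjusted island tests.
* **Demographic nulls** — a structured-coalescent simulator (piecewise
  sizes, splits, migration; recombination via block independence) driving
  null distributions of π and F<sub>ST</sub> over a 0–250 cM/Mb grid,
  Mann–Whitney comparisons, SFS goodness of fit, and moment estimators
  N̂<sub>e</sub> = θ<sub>W</sub>/4μ<sub>g</sub> and T̂ = d<sub>a</sub>/2μ<sub>y</sub>.
* **Space and LD** — Mantel tests with row/column permutation, 10-km
  binned weighted IBD regression with bootstrap SEs, r² within 50 kb,
  Hill–Weir decay fits, and 50-SNP/5-step/0.2 LD pruning.

The synthetic-data generator emulates the study design end to end: four
populations under an isolation-with-migration demography, balanced and
sorted haplogroup signals injected by grafting deep ancestral structure,
near-haploid inbred genotypes, an outgroup, and a sequencing depth/error
layer emitted as VCF v4.2 (GT:DP:AD) plus metadata, callable-site and
truth files.

## Worked example

Simulate a 500-window genome with one balanced and one sorted region,
run the scan, and test the island signal:

```r
library(popgenscan)

model <- default_demography(n_diploid = 10)
cfg <- simulation_config(
  n_windows = 500, seed = 11,
  signal_specs = list(
    signal_spec("balanced", windows = 101:110),
    signal_spec("sorted",   windows = 301:308,
                freq_A = c(WES = 1, COL = 1, UTA = 0, NOR = 0))))

ex <- scan_experiment(model, cfg)
sc <- scan_pi_islands(ex$stats)
sc$regions$runs
#>   chrom  start    end n_windows
#> 1  chr2 560000 760000        10

fs <- scan_fst_islands(ex$stats, mask = sc$regions)
head(fs$islands$WES_UTA$windows$window)
#> [1] 301 302 303 304 305 306

r <- randomization_test(fs$stats$dxy_WES_UTA,
                        fs$stats$window %in% fs$islands$WES_UTA$windows$window,
                        n_perm = 4999)
c(observed = r$observed, p = r$p_value)
#>    observed           p
#> 0.009159566 0.000200000
```

The merged shared-π-island region reproduces the injected balanced region
exactly (windows 101–110 of chr2); the sorted windows are recovered as
F<sub>ST</sub>-islands in the pairs that carry opposite haplogroups, and
island d<sub>XY</sub> exceeds the genomic background at the smallest
P the permutation count allows — the joint F<sub>ST</sub>/d<sub>XY</sub>
elevation that distinguishes sorted ancestral variation from
differential gene flow.

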