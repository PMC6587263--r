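#' Genotype and site filter configuration
#'
#' Default thresholds follow the stringent genotype-quality filters for a
#' predominantly inbreeding species: homozygous calls need at least 2
#' supporting reads, heterozygous calls at least 20 reads and a reference
#' read fraction within \[0.25, 0.75\]; sites are dropped when genotyped in
#' fewer than 50% of samples, when mean depth exceeds 20, when more than
#' one alternative allele is present, when more than 15% of genotypes are
#' heterozygous (a paralogy signal in an inbreeder), or when alleles are
#' indels; samples with more than 60% missing genotypes are removed.
#'
#' @param hom_min_depth,het_min_depth minimum supporting reads.
#' @param ref_fraction_bounds heterozygote reference-read fraction bounds.
#' @param site_max_missing maximum fraction of missing genotypes per site.
#' @param site_max_mean_depth maximum mean depth (over non-missing calls).
#' @param site_max_het_fraction maximum heterozygous-genotype fraction.
#' @param sample_max_missing maximum per-sample missing fraction.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(hom_min_depth = 2, het_min_depth = 20,
                          ref_fraction_bounds = c(0.25, 0.75),
                          site_max_missing = 0.50,
                          site_max_mean_depth = 20,
                          site_max_het_fraction = 0.15,
                          sample_max_missing = 0.60) {
  stopifnot(ref_fraction_bounds[1] <= ref_fraction_bounds[2],
            hom_min_depth >= 0, het_min_depth >= 0,
            site_max_missing >= 0, site_max_mean_depth >= 0,
            site_max_het_fraction >= 0, sample_max_missing >= 0)
  structure(list(hom_min_depth = hom_min_depth,
                 het_min_depth = het_min_depth,
                 ref_fraction_bounds = ref_fraction_bounds,
                 site_max_missing = site_max_missing,
                 site_max_mean_depth = site_max_mean_depth,
                 site_max_het_fraction = site_max_het_fraction,
                 sample_max_missing = sample_max_missing),
            class = "filter_config")
}

#' Mask low-confidence genotypes
#'
#' Sets to missing: homozygous calls supported by fewer than
#' `hom_min_depth` reads; heterozygous calls supported by fewer than
#' `het_min_depth` reads; heterozygous calls whose reference read fraction
#' `AD_ref / (AD_ref + AD_alt)` falls outside `ref_fraction_bounds`. The
#' bounds are applied to the reference read *fraction* (a printed ref/alt
#' ratio of 1.0 would reject perfectly balanced heterozygotes, which
#' contradicts the filter's intent). All other calls are unchanged.
#'
#' @param gm a `genotype_matrix` with `dp` and `ad_*` present.
#' @param cfg a [filter_config()].
#' @return the masked `genotype_matrix`.
#' @export
mask_genotypes <- function(gm, cfg = filter_config()) {
  if (is.null(gm$dp) || is.null(gm$ad_ref) || is.null(gm$ad_alt))
    stop("mask_genotypes requires DP and AD fields in the genotype matrix")
  gt <- gm$gt
  hom <- !is.na(gt) & gt != 1L
  het <- !is.na(gt) & gt == 1L
  dp <- gm$dp
  gt[hom & (is.na(dp) | dp < cfg$hom_min_depth)] <- NA
  gt[het & (is.na(dp) | dp < cfg$het_min_depth)] <- NA
  rf <- gm$ad_ref / (gm$ad_ref + gm$ad_alt)
  bad_rf <- het & !is.na(rf) &
    (rf < cfg$ref_fraction_bounds[1] | rf > cfg$ref_fraction_bounds[2])
  gt[bad_rf] <- NA
  gm$gt <- gt
  gm
}

#' Filter sites
#'
#' Removes sites that are missing in at least `site_max_missing` of
#' samples, have mean depth (over non-missing genotypes) above
#' `site_max_mean_depth`, carry more than one alternative allele, have a
#' heterozygous-genotype fraction above `site_max_het_fraction`, or are
#' indels. Each removed site gets exactly one reason, the first matching in
#' that order, so the ledger is deterministic.
#'
#' @param gm a masked `genotype_matrix`.
#' @param cfg a [filter_config()].
#' @return list with `matrix` (retained sites) and `ledger`
#'   (data.frame chrom, pos, reason for removed sites).
#' @export
filter_sites <- function(gm, cfg = filter_config()) {
  gt <- gm$gt
  n <- nrow(gt)
  n_called <- colSums(!is.na(gt))
  miss_frac <- 1 - n_called / n
  mean_dp <- if (!is.null(gm$dp)) {
    dpna <- gm$dp
    dpna[is.na(gt)] <- NA
    colMeans(dpna, na.rm = TRUE)
  } else rep(0, ncol(gt))
  het_frac <- ifelse(n_called > 0,
                     colSums(gm$gt == 1L, na.rm = TRUE) / n_called, 0)
  reason <- rep(NA_character_, ncol(gt))
  reason[is.na(reason) & miss_frac >= cfg$site_max_missing] <- "missingness"
  reason[is.na(reason) & !is.na(mean_dp) &
           mean_dp > cfg$site_max_mean_depth] <- "mean_depth"
  reason[is.na(reason) & gm$n_alt_alleles > 1L] <- "multiallelic"
  reason[is.na(reason) & het_frac > cfg$site_max_het_fraction] <- "het_fraction"
  reason[is.na(reason) & !gm$is_snp] <- "indel"
  keep <- is.na(reason)
  ledger <- data.frame(chrom = gm$chrom[!keep], pos = gm$pos[!keep],
                       reason = reason[!keep])
  list(matrix = subset_sites(gm, keep), ledger = ledger)
}

subset_sites <- function(gm, keep) {
  for (f in c("gt", "dp", "ad_ref", "ad_alt"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][, keep, drop = FALSE]
  for (f in c("chrom", "pos", "ref", "alt", "n_alt_alleles", "is_snp"))
    gm[[f]] <- gm[[f]][keep]
  gm
}

subset_samples <- function(gm, keep) {
  for (f in c("gt", "dp", "ad_ref", "ad_alt"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][keep, , drop = FALSE]
  gm$samples <- gm$samples[keep]
  gm
}

#' Filter samples by missingness
#'
#' Removes samples whose missing-genotype fraction exceeds
#' `sample_max_missing`; the order of remaining samples is preserved.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [filter_config()].
#' @return list with `matrix` and `removed` (sample names).
#' @export
filter_samples <- function(gm, cfg = filter_config()) {
  miss <- rowMeans(is.na(gm$gt))
  drop <- miss > cfg$sample_max_missing
  if (all(drop)) stop("all samples exceed the missingness threshold")
  list(matrix = subset_samples(gm, !drop), removed = gm$samples[drop])
}

#' Genotype concordance against a truth set
#'
#' Per compared position-sample cell: TP if the called genotype equals the
#' truth; FHET if they differ and at least one of the two is heterozygous;
#' FHOM if they are different homozygotes; MISS if the query is uncalled.
#' TPR = TP/(TP+FHET+FHOM), FR = (FHET+FHOM)/(TP+FHET+FHOM),
#' MR = MISS/(TP+FHET+FHOM+MISS). With no called genotypes TPR and FR are
#' NaN while the counts remain intact.
#'
#' @param calls,truth `genotype_matrix` objects (or bare dosage matrices)
#'   with identical samples and positions.
#' @return object of class `concordance_report` (a list of counts and rates).
#' @export
concordance <- function(calls, truth) {
  gq <- if (inherits(calls, "genotype_matrix")) calls$gt else as.matrix(calls)
  gt <- if (inherits(truth, "genotype_matrix")) truth$gt else as.matrix(truth)
  if (!all(dim(gq) == dim(gt)))
    stop("calls and truth must cover the same samples and positions")
  if (inherits(calls, "genotype_matrix") && inherits(truth, "genotype_matrix")) {
    if (!identical(calls$samples, truth$samples))
      stop("sample mismatch between calls and truth")
    if (!identical(calls$pos, truth$pos) || !identical(calls$chrom, truth$chrom))
      stop("position mismatch between calls and truth")
  }
  miss <- is.na(gq) & !is.na(gt)
  both <- !is.na(gq) & !is.na(gt)
  tp <- both & gq == gt
  diff <- both & gq != gt
  fhet <- diff & (gq == 1L | gt == 1L)
  fhom <- diff & !fhet
  TP <- sum(tp); FHET <- sum(fhet); FHOM <- sum(fhom); MISS <- sum(miss)
  called <- TP + FHET + FHOM
  structure(list(TP = TP, FHET = FHET, FHOM = FHOM, MISS = MISS,
                 TPR = TP / called, FR = (FHET + FHOM) / called,
                 MR = MISS / (called + MISS)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: TP=%d FHET=%d FHOM=%d MISS=%d\n",
              x$TP, x$FHET, x$FHOM, x$MISS))
  cat(sprintf("  TPR=%.4f FR=%.4f MR=%.4f\n", x$TPR, x$FR, x$MR))
  invisible(x)
}

#' Write a site-filter ledger to TSV
#' @param ledger data.frame from [filter_sites()].
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
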