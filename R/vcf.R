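#' Genomic layout of simulated windows
#'
#' Tiles the configured number of windows sequentially onto
#' `n_chromosomes` chromosomes (`chr1`, `chr2`, ...), as 0-based half-open
#' intervals of the configured window length.
#'
#' @param config a `simulation_config`.
#' @return data.frame (window, chrom, start, end).
#' @export
window_layout <- function(config) {
  n <- config$n_windows
  k <- config$n_chromosomes
  per <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  chrom <- rep(paste0("chr", seq_len(k)), per)
  within <- unlist(lapply(per, seq_len)) - 1L
  data.frame(window = seq_len(n), chrom = chrom,
             start = within * config$window_length_bp,
             end = (within + 1L) * config$window_length_bp)
}

#' Render simulated genotypes to VCF with a sequencing depth/error layer
#'
#' Per-genotype depth is Poisson(`mean_depth`); allelic depths for true
#' heterozygotes are Binomial(depth, `het_balance`); each read is misread
#' as the other allele with probability `base_error_rate`. Genotypes are
#' re-called from the simulated reads (both alleles seen = heterozygote,
#' zero depth = missing), so low depth produces missingness and sequencing
#' error produces false heterozygotes. Writes a VCF v4.2 (GT:DP:AD), a
#' per-window callable-site TSV, truth-region BED and a truth genotype TSV;
#' with a fixed config seed the files are byte-identical across runs.
#'
#' @param gsims a `genotype_sims` from [collapse_to_inbred()].
#' @param dir output directory (created if needed).
#' @param depth_model overrides the config's depth model if given.
#' @return invisible list with file `paths` and the `truth` set
#'   (per-window true dosage matrices, signal regions, per-sample pairing).
#' @export
render_vcf <- function(gsims, dir, depth_model = NULL) {
  stopifnot(inherits(gsims, "genotype_sims"))
  dm <- depth_model %||% gsims$config$depth_model
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lay <- window_layout(gsims$config)
  n_samp <- length(gsims$samples)
  L <- gsims$config$window_length_bp

  vcf_path <- file.path(dir, "sim.vcf")
  call_path <- file.path(dir, "callable.tsv")
  truth_bed <- file.path(dir, "truth_regions.bed")
  truth_tsv <- file.path(dir, "truth_genotypes.tsv")

  con <- file(vcf_path, "wb")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popgenscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gsims$samples), collapse = "\t")),
             con, sep = "\n")

  # per-site callability: depth >= 1 in at least 50% of samples
  p_cov <- 1 - exp(-dm$mean_depth)
  p_site <- 1 - pbinom(ceiling(n_samp / 2) - 1, n_samp, p_cov)

  call_tab <- lay
  call_tab$n_callable <- 0L
  truth_rows <- list()

  for (w in seq_along(gsims$windows)) {
    win <- gsims$windows[[w]]
    S <- length(win$pos)
    gpos <- lay$start[w] + win$pos
    call_tab$n_callable[w] <- rbinom(1, L, p_site)
    if (S == 0) next
    g <- win$geno                       # samples x sites dosage
    d <- matrix(rpois(n_samp * S, dm$mean_depth), n_samp, S)
    # reads supporting ref before error: hom ref -> d, het -> Binom(d, bal)
    r_true <- matrix(0L, n_samp, S)
    hom_ref <- g == 0L; het <- g == 1L
    r_true[hom_ref] <- d[hom_ref]
    if (any(het))
      r_true[het] <- rbinom(sum(het), d[het], dm$het_balance)
    a_true <- d - r_true
    # per-read error flips
    err <- dm$base_error_rate
    flip_r <- matrix(rbinom(n_samp * S, as.vector(r_true), err), n_samp, S)
    flip_a <- matrix(rbinom(n_samp * S, as.vector(a_true), err), n_samp, S)
    r_obs <- r_true - flip_r + flip_a
    a_obs <- d - r_obs
    gt <- ifelse(d == 0L, "./.",
          ifelse(r_obs > 0L & a_obs > 0L, "0/1",
          ifelse(a_obs > 0L, "1/1", "0/0")))
    field <- matrix(paste0(gt, ":", d, ":", r_obs, ",", a_obs), n_samp, S)
    lines <- paste(lay$chrom[w], gpos, ".", "A", "T", ".", "PASS", ".",
                   "GT:DP:AD",
                   apply(field, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con, sep = "\n")
    truth_rows[[w]] <- data.frame(chrom = lay$chrom[w], pos = gpos,
                                  t(win$geno))
  }
  close(con)

  write.table(call_tab[, c("chrom", "start", "end", "n_callable")],
              call_path, sep = "\t", quote = FALSE, row.names = FALSE)

  sw <- gsims$signal_windows
  bed <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0))
  if (length(sw)) {
    bed <- data.frame(chrom = lay$chrom[sw], start = lay$start[sw],
                      end = lay$end[sw],
                      name = unname(gsims$signal_kinds[as.character(sw)]))
  }
  write.table(bed, truth_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tg <- do.call(rbind, truth_rows)
  if (!is.null(tg)) colnames(tg) <- c("chrom", "pos", gsims$samples)
  write.table(tg, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(paths = list(vcf = vcf_path, callable = call_path,
                              truth_regions = truth_bed,
                              truth_genotypes = truth_tsv),
                 truth = list(genotypes = tg, regions = bed,
                              windows = gsims$windows)))
}

#' Read a VCF into a genotype matrix
#'
#' Thin wrapper over `vcfR`: extracts GT as dosage (0/1/2, NA for missing),
#' DP and the two AD fields for biallelic records. Multi-allelic or indel
#' records are kept with a flag so that site filters can remove them.
#'
#' @param path VCF file path.
#' @return object of class `genotype_matrix`: list with matrices `gt`,
#'   `dp`, `ad_ref`, `ad_alt` (samples x sites), vectors `chrom`, `pos`,
#'   `ref`, `alt`, `samples`, and logical `is_snp`.
#' @export
read_genotype_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- t(vcfR::extract.gt(v, element = "GT"))
  dp <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- t(vcfR::extract.gt(v, element = "AD"))
  ad_ref <- matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad))
  ad_alt <- matrix(suppressWarnings(as.integer(sub("^[^,]*,", "", ad))),
                   nrow(ad), ncol(ad))
  a1 <- substr(gt_raw, 1, 1); a2 <- substr(gt_raw, 3, 3)
  gt <- suppressWarnings(as.integer(a1) + as.integer(a2))
  gt <- matrix(gt, nrow(gt_raw), ncol(gt_raw))
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  is_snp <- !grepl(",", alt) & nchar(ref) == 1L &
    nchar(alt) == 1L & alt != "." & !is.na(alt)
  structure(list(gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
                 chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                 ref = ref, alt = alt,
                 samples = rownames(gt_raw),
                 n_alt_alleles = ifelse(is.na(alt) | alt == ".", 0L,
                                        nchar(gsub("[^,]", "", alt)) + 1L),
                 is_snp = is_snp),
            class = "genotype_matrix")
}

#' Construct a genotype matrix in memory
#'
#' @param gt samples x sites dosage matrix (0/1/2, NA missing).
#' @param chrom,pos site coordinates.
#' @param dp,ad_ref,ad_alt optional per-genotype depth and allelic depths.
#' @param samples sample names.
#' @param is_snp logical per site (default all TRUE).
#' @param n_alt_alleles integer per site (default 1).
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, chrom, pos, dp = NULL, ad_ref = NULL,
                            ad_alt = NULL, samples = NULL, is_snp = NULL,
                            n_alt_alleles = NULL) {
  gt <- as.matrix(gt)
  structure(list(gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
                 chrom = as.character(chrom), pos = as.integer(pos),
                 ref = rep("A", ncol(gt)), alt = rep("T", ncol(gt)),
                 samples = samples %||% rownames(gt) %||%
                   paste0("s", seq_len(nrow(gt))),
                 n_alt_alleles = n_alt_alleles %||% rep(1L, ncol(gt)),
                 is_snp = is_snp %||% rep(TRUE, ncol(gt))),
            class = "genotype_matrix")
}

#' @importFrom stats pbinom
NULL
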