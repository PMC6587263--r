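#' Partition scaffolds into non-overlapping windows
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @param window_length window length in bp (default 20,000).
#' @return data.frame (chrom, start, end), 0-based half-open; the terminal
#'   window of a scaffold may be shorter.
#' @export
partition_windows <- function(scaffold_lengths, window_length = 20000L) {
  stopifnot(all(scaffold_lengths > 0))
  nm <- names(scaffold_lengths) %||% paste0("scaffold", seq_along(scaffold_lengths))
  out <- lapply(seq_along(scaffold_lengths), function(i) {
    len <- scaffold_lengths[i]
    starts <- seq(0, len - 1, by = window_length)
    data.frame(chrom = nm[i], start = starts,
               end = pmin(starts + window_length, len))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Window eligibility flags
#'
#' A window is eligible for basic statistics with at least 5,000 callable
#' sites; for segregating-site statistics (Tajima's D, FST) with, in
#' addition, at least 20 SNPs; and for outgroup statistics (Fay & Wu's H,
#' RND) with at least 2,000 outgroup-aligned bases.
#'
#' @param n_callable,n_snps,n_outgroup_aligned per-window counts.
#' @param min_callable,min_snps,min_outgroup thresholds.
#' @return data.frame of logical flags (basic, segregating, outgroup).
#' @export
window_eligibility <- function(n_callable, n_snps, n_outgroup_aligned,
                               min_callable = 5000L, min_snps = 20L,
                               min_outgroup = 2000L) {
  basic <- n_callable >= min_callable
  data.frame(basic = basic,
             segregating = basic & n_snps >= min_snps,
             outgroup = basic & n_outgroup_aligned >= min_outgroup)
}

#' Randomly haploidize diploid genotypes
#'
#' One allele is chosen uniformly at random per heterozygous call;
#' homozygotes map deterministically; missing stays missing.
#' Seed-reproducible via the global RNG.
#'
#' @param gt samples x sites dosage matrix (0/1/2, NA) or a
#'   `genotype_matrix`.
#' @return haploid 0/1/NA matrix of the same shape.
#' @export
haploidize <- function(gt) {
  if (inherits(gt, "genotype_matrix")) gt <- gt$gt
  h <- gt
  h[gt == 2L] <- 1L
  het <- which(gt == 1L)
  if (length(het)) h[het] <- rbinom(length(het), 1L, 0.5)
  h
}

# per-site derived counts and sample sizes from a haploid 0/1/NA matrix
site_counts <- function(hap) {
  if (!is.matrix(hap)) hap <- matrix(hap, nrow = 1)
  n <- colSums(!is.na(hap))
  i <- colSums(hap == 1L, na.rm = TRUE)
  list(n = n, i = i)
}

#' Per-site nucleotide diversity in a window
#'
#' `pi = sum_sites 2 i (n - i) / (n (n - 1)) / n_callable`, with `n` the
#' per-site non-missing haploid count and `i` the alternate-allele count;
#' monomorphic callable sites enter the denominator.
#'
#' @param hap haploid 0/1/NA matrix (rows = haplotypes) holding the
#'   window's segregating sites.
#' @param n_callable callable sites in the window (denominator).
#' @return per-site pi (NA when `n_callable` is 0).
#' @export
window_pi <- function(hap, n_callable) {
  if (is.na(n_callable) || n_callable <= 0) return(NA_real_)
  sc <- site_counts(hap)
  pi_total_from_counts(sc$i, sc$n) / n_callable
}

pi_total_from_counts <- function(i, n) {
  ok <- n >= 2
  sum(2 * i[ok] * (n[ok] - i[ok]) / (n[ok] * (n[ok] - 1)))
}

tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Watterson's theta and Tajima's D for a window
#'
#' `thetaW = S / (a1 * n_callable)` per site, with `a1` the harmonic number
#' of `n - 1`; `D = (pi_total - thetaW_total) / sqrt(e1 S + e2 S (S - 1))`
#' with the classic constants. `n` is taken as the window-median per-site
#' non-missing haploid count; D is missing when `S = 0`.
#'
#' @param hap haploid 0/1/NA matrix of the window's segregating sites.
#' @param n_callable callable sites in the window.
#' @return list `(theta_w, tajima_d, S, n)`.
#' @export
window_theta_d <- function(hap, n_callable) {
  sc <- site_counts(hap)
  seg <- sc$i > 0 & sc$i < sc$n
  S <- sum(seg)
  n <- if (any(seg)) as.integer(round(median(sc$n[seg]))) else
    as.integer(round(median(sc$n)))
  if (S == 0 || is.na(n) || n < 2)
    return(list(theta_w = if (S == 0) 0 else NA_real_, tajima_d = NA_real_,
                S = S, n = n))
  k <- tajima_constants(n)
  theta_w_total <- S / k$a1
  pi_total <- pi_total_from_counts(sc$i, sc$n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(theta_w = theta_w_total / n_callable,
       tajima_d = (pi_total - theta_w_total) / denom,
       S = S, n = n)
}

#' Unnormalized Fay & Wu's H for a window
#'
#' Sites are polarized against the outgroup allele (derived = allele
#' different from the outgroup); sites with a missing outgroup allele are
#' excluded. `H = theta_pi - theta_H`, with
#' `theta_H = sum_sites 2 i^2 / (n (n - 1))` over derived counts `i`.
#' Negative H marks an excess of high-frequency derived alleles.
#'
#' @param hap haploid 0/1/NA matrix of the window's segregating sites.
#' @param outgroup outgroup allele (0/1/NA) per site.
#' @return H, or NA when no site can be polarized.
#' @export
window_fay_wu_h <- function(hap, outgroup) {
  sc <- site_counts(hap)
  ok <- !is.na(outgroup) & sc$n >= 2
  if (!any(ok)) return(NA_real_)
  n <- sc$n[ok]
  derived <- ifelse(outgroup[ok] == 0L, sc$i[ok], sc$n[ok] - sc$i[ok])
  theta_pi <- sum(2 * derived * (n - derived) / (n * (n - 1)))
  theta_h <- sum(2 * derived^2 / (n * (n - 1)))
  theta_pi - theta_h
}

#' Downsample a haploid matrix to a fixed site-frequency spectrum
#'
#' Per site and population, exactly `target` alleles are drawn without
#' replacement from the non-missing alleles; sites with fewer non-missing
#' alleles than the target in any population are discarded and counted.
#' Folding uses the minor-allele count (an exact 50% tie falls in the
#' highest folded class once).
#'
#' @param hap haploid 0/1/NA matrix of segregating sites.
#' @param pops factor of population labels per row.
#' @param targets named integer vector of projected haploid sample sizes
#'   (defaults echo a four-group design: 39, 78, 63, 52).
#' @param fold logical; folded (minor-allele) or unfolded (derived) SFS.
#'   Unfolded assumes rows are already polarized (1 = derived).
#' @return object of class `sfs`: per-population count vectors, the
#'   discard ledger (`n_sites_discarded`), orientation and targets.
#' @export
downsampled_sfs <- function(hap, pops, targets = NULL, fold = TRUE) {
  pops <- as.factor(pops)
  pn <- levels(pops)
  if (is.null(targets))
    targets <- setNames(c(39L, 78L, 63L, 52L)[seq_along(pn)], pn)
  if (!all(pn %in% names(targets))) stop("targets must cover every population")
  targets <- targets[pn]
  for (p in pn)
    if (targets[[p]] > sum(pops == p))
      stop(sprintf("target %d exceeds sample size of population %s",
                   targets[[p]], p))
  S <- ncol(hap)
  cnt <- lapply(pn, function(p) {
    h <- hap[pops == p, , drop = FALSE]
    sc <- site_counts(h)
    sc
  })
  names(cnt) <- pn
  keep <- rep(TRUE, S)
  for (p in pn) keep <- keep & cnt[[p]]$n >= targets[[p]]
  spectra <- list()
  for (p in pn) {
    tg <- targets[[p]]
    len <- if (fold) floor(tg / 2) + 1L else tg + 1L
    counts <- integer(len)
    if (any(keep)) {
      nn <- cnt[[p]]$n[keep]; ii <- cnt[[p]]$i[keep]
      # hypergeometric draw of derived alleles among tg sampled
      d <- rhyper_vec(ii, nn - ii, tg)
      cls <- if (fold) pmin(d, tg - d) else d
      tb <- tabulate(cls + 1L, nbins = len)
      counts <- tb
    }
    spectra[[p]] <- setNames(counts, seq_len(len) - 1L)
  }
  structure(list(spectra = spectra,
                 orientation = if (fold) "folded" else "unfolded",
                 targets = targets,
                 n_sites_used = sum(keep),
                 n_sites_discarded = sum(!keep)),
            class = "sfs")
}

rhyper_vec <- function(white, black, k) {
  if (!length(white)) return(integer(0))
  mapply(function(w, b) stats::rhyper(1, w, b, k), white, black)
}

#' Fold an unfolded spectrum
#' @param counts unfolded counts, classes 0..n.
#' @return folded counts, classes 0..floor(n/2).
#' @export
fold_sfs <- function(counts) {
  n <- length(counts) - 1L
  len <- floor(n / 2) + 1L
  out <- numeric(len)
  for (d in 0:n) {
    cls <- min(d, n - d)
    out[cls + 1L] <- out[cls + 1L] + counts[d + 1L]
  }
  setNames(out, seq_len(len) - 1L)
}

#' Coding-sequence length per window
#'
#' Sums the merged CDS overlap with each window. Annotation is read from a
#' GFF3 file (via `rtracklayer`) or given directly as a `GRanges`.
#'
#' @param windows data.frame (chrom, start, end), 0-based half-open.
#' @param annotation GFF3 path or `GRanges` with a `type` column.
#' @return integer vector of CDS bp per window.
#' @export
gene_density <- function(windows, annotation) {
  if (is.character(annotation)) {
    check_gff3(annotation)
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  cds <- annotation[as.character(annotation$type) == "CDS"]
  cds <- GenomicRanges::reduce(cds, ignore.strand = TRUE)
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  ov <- GenomicRanges::findOverlaps(win, cds)
  if (!length(ov)) return(rep(0L, nrow(windows)))
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(win)[S4Vectors::queryHits(ov)],
    IRanges::ranges(cds)[S4Vectors::subjectHits(ov)]))
  out <- rep(0L, nrow(windows))
  agg <- tapply(w, S4Vectors::queryHits(ov), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

check_gff3 <- function(path) {
  ln <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", ln) & nzchar(ln))
  bad <- body[vapply(strsplit(ln[body], "\t"), length, 1L) != 9L]
  if (length(bad))
    stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated fields",
                 bad[1]))
  invisible(TRUE)
}
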