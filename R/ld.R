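#' Pairwise r-squared within a distance bound
#'
#' For every pair of common SNPs (both minor allele frequencies at least
#' `maf_min`) on the same chromosome and within `max_dist` bp, computes the
#' squared Pearson correlation of allele dosages across individuals with
#' pairwise-complete genotypes.
#'
#' @param gt samples x sites dosage matrix (or `genotype_matrix`).
#' @param chrom,pos site coordinates (taken from the `genotype_matrix`
#'   when omitted).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_dist maximum pair distance in bp (default 50,000).
#' @return data.frame (chrom, pos1, pos2, dist, r2).
#' @export
ld_r2 <- function(gt, chrom = NULL, pos = NULL, maf_min = 0.05,
                  max_dist = 50000) {
  if (inherits(gt, "genotype_matrix")) {
    chrom <- chrom %||% gt$chrom
    pos <- pos %||% gt$pos
    gt <- gt$gt
  }
  gt <- as.matrix(gt)
  ploidy <- max(gt, na.rm = TRUE)
  if (ploidy < 1) ploidy <- 1
  p <- colMeans(gt, na.rm = TRUE) / ploidy
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  gt <- gt[, keep, drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(pos[idx])]
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      jj <- ii + 1L
      while (jj <= length(idx) && pos[idx[jj]] - pos[i] <= max_dist) {
        j <- idx[jj]
        r <- suppressWarnings(
          cor(gt[, i], gt[, j], use = "pairwise.complete.obs"))
        out[[length(out) + 1L]] <-
          data.frame(chrom = ch, pos1 = pos[i], pos2 = pos[j],
                     dist = pos[j] - pos[i], r2 = r^2)
        jj <- jj + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), dist = integer(0), r2 = numeric(0)))
  do.call(rbind, out)
}

#' Expected r-squared under the Hill & Weir drift-recombination model
#'
#' The classic expectation for r^2 between sites at population-scaled
#' recombination distance `C = rho * d`, including the 1/n finite-sample
#' term:
#' `E[r2] = (10 + C) / ((2 + C) (11 + C)) *
#'   (1 + ((3 + C) (12 + 12 C + C^2)) / (n (2 + C) (11 + C)))`.
#'
#' @param C population-scaled recombination distance (4 Ne c d).
#' @param n sample size (number of sequences).
#' @return expected r^2.
#' @export
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill & Weir decay curve to observed r-squared
#'
#' Nonlinear least squares of observed r^2 against
#' [hill_weir_expectation()] with `C = rho * dist`, estimating the
#' per-bp population recombination parameter `rho >= 0`. Also reports the
#' half-decay distance (where the fitted curve falls to half its
#' zero-distance value; infinite if never reached).
#'
#' @param pairs data.frame from [ld_r2()] (needs `dist`, `r2`).
#' @param n sample size used for the finite-sample term.
#' @param rho_start starting value (default 1e-3).
#' @return list `(rho, half_decay_bp, fitted, converged)`.
#' @export
hill_weir_fit <- function(pairs, n, rho_start = 1e-3) {
  stopifnot(nrow(pairs) >= 50, length(unique(pairs$dist)) >= 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ hill_weir_expectation(rho * dist, n),
                      data = pairs, start = list(rho = rho_start),
                      lower = c(rho = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("Hill-Weir fit failed to converge: %s", conditionMessage(e))))
  rho <- coef(fit)[["rho"]]
  r2_0 <- hill_weir_expectation(0, n)
  half <- Inf
  if (rho > 0) {
    f <- function(d) hill_weir_expectation(rho * d, n) - r2_0 / 2
    lim <- hill_weir_expectation(rho * 1e9, n)
    if (f(1e9) < 0)
      half <- stats::uniroot(f, c(0, 1e9))$root
  }
  list(rho = rho, half_decay_bp = half,
       fitted = stats::fitted(fit), converged = TRUE)
}

#' Greedy LD pruning
#'
#' Scans position-sorted SNPs in sliding windows of `window` SNPs advancing
#' by `step`; within each window, for any retained pair with
#' `r^2 > r2_max` the later (higher-position) SNP is removed. The surviving
#' set has no retained within-window pair above the threshold.
#'
#' @param gt samples x sites dosage matrix (or `genotype_matrix`).
#' @param pos site positions (from the `genotype_matrix` when omitted).
#' @param window window size in SNPs (default 50).
#' @param step advance in SNPs (default 5).
#' @param r2_max pruning threshold (default 0.2).
#' @return integer indices (into the input columns) of the kept SNPs.
#' @export
ld_prune <- function(gt, pos = NULL, window = 50, step = 5, r2_max = 0.2) {
  if (inherits(gt, "genotype_matrix")) {
    pos <- pos %||% gt$pos
    gt <- gt$gt
  }
  gt <- as.matrix(gt)
  S <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(S)
  if (is.unsorted(pos)) stop("SNPs must be position-sorted")
  keep <- rep(TRUE, S)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, S)
    idx <- (start:end)[keep[start:end]]
    if (length(idx) > 1) {
      for (ai in seq_len(length(idx) - 1L)) {
        i <- idx[ai]
        if (!keep[i]) next
        for (bi in (ai + 1L):length(idx)) {
          j <- idx[bi]
          if (!keep[j]) next
          r <- suppressWarnings(
            cor(gt[, i], gt[, j], use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_max) keep[j] <- FALSE
        }
      }
    }
    if (end >= S) break
    start <- start + step
  }
  which(keep)
}
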