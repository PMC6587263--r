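#' Weir & Cockerham weighted FST for a window
#'
#' Per segregating site the Weir & Cockerham (1984) variance components are
#' computed for the two populations — `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals, from
#' observed heterozygosity) — and the window estimate is the
#' "ratio of averages" `sum(a) / sum(a + b + c)` over retained sites, never
#' the mean of per-site ratios. Sites genotyped in fewer than 50% of
#' individuals in either population are excluded; sites with a zero total
#' component are skipped. Haploid input (`ploidy = 1`) is treated as fully
#' homozygous diploids, so `c = 0`.
#'
#' @param geno individuals x sites matrix: dosage 0/1/2 (NA missing) for
#'   `ploidy = 2`, alleles 0/1 for `ploidy = 1`.
#' @param pops factor of population labels per row (exactly 2 levels used).
#' @param pair character vector of the two population names (default: the
#'   first two levels).
#' @param ploidy 1 or 2.
#' @param min_called_frac per-population minimum genotyped fraction per
#'   site (default 0.5).
#' @return list `(fst, num, den, n_sites)`; `fst` is NA when no site is
#'   usable or a population never has two genotyped individuals.
#' @export
wc_fst_window <- function(geno, pops, pair = NULL, ploidy = 2,
                          min_called_frac = 0.5) {
  pops <- as.factor(pops)
  if (is.null(pair)) pair <- levels(pops)[1:2]
  g1 <- geno[pops == pair[1], , drop = FALSE]
  g2 <- geno[pops == pair[2], , drop = FALSE]
  if (ploidy == 1) { g1 <- g1 * 2L; g2 <- g2 * 2L }
  comp <- wc_components(g1, g2, min_called_frac)
  if (is.null(comp)) return(list(fst = NA_real_, num = NA_real_,
                                 den = NA_real_, n_sites = 0L))
  num <- sum(comp$a); den <- sum(comp$a + comp$b + comp$c)
  list(fst = if (den > 0) num / den else NA_real_,
       num = num, den = den, n_sites = length(comp$a))
}

# W&C 1984 two-allele components per site from two dosage matrices
wc_components <- function(g1, g2, min_called_frac = 0.5) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  if (all(n1 < 2) || all(n2 < 2)) return(NULL)
  ok <- n1 >= pmax(2, min_called_frac * nrow(g1)) &
        n2 >= pmax(2, min_called_frac * nrow(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
  poly <- ok & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(poly)) return(list(a = numeric(0), b = numeric(0), c = numeric(0)))
  n1 <- n1[poly]; n2 <- n2[poly]; p1 <- p1[poly]; p2 <- p2[poly]
  h1 <- h1[poly]; h2 <- h2[poly]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Absolute divergence dXY for a window
#'
#' Per site `d = p1 (1 - p2) + p2 (1 - p1)` (mean pairwise difference
#' between one allele from each population); the window value averages over
#' all callable sites, variable and monomorphic. Sites failing the
#' per-population 50%-genotyped rule are excluded from numerator and
#' denominator.
#'
#' @param hap haploid 0/1/NA matrix of the window's segregating sites.
#' @param pops factor per row.
#' @param pair the two population names.
#' @param n_callable callable sites in the window.
#' @return per-site dXY (NA when no callable sites).
#' @export
dxy_window <- function(hap, pops, pair = NULL, n_callable) {
  pops <- as.factor(pops)
  if (is.null(pair)) pair <- levels(pops)[1:2]
  h1 <- hap[pops == pair[1], , drop = FALSE]
  h2 <- hap[pops == pair[2], , drop = FALSE]
  s1 <- site_counts(h1); s2 <- site_counts(h2)
  ok <- s1$n >= pmax(1, 0.5 * nrow(h1)) & s2$n >= pmax(1, 0.5 * nrow(h2))
  denom <- n_callable - sum(!ok)
  if (is.na(denom) || denom <= 0) return(NA_real_)
  p1 <- s1$i[ok] / s1$n[ok]
  p2 <- s2$i[ok] / s2$n[ok]
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / denom
}

#' Net divergence da
#'
#' `da = dXY - (piX + piY) / 2`; under clean isolation `E[da] = 2 mu T`.
#'
#' @param dxy,pi_x,pi_y per-site window statistics.
#' @return da (NA if any input is missing).
#' @export
da_window <- function(dxy, pi_x, pi_y) {
  ifelse(is.na(dxy) | is.na(pi_x) | is.na(pi_y),
         NA_real_, dxy - (pi_x + pi_y) / 2)
}

#' Relative node depth
#'
#' `RND = dXY / ((dX_out + dY_out) / 2)`: divergence between two
#' populations normalized by their mean divergence to an outgroup, which
#' cancels local mutation-rate variation. Missing (with a warning) when the
#' outgroup divergence is zero.
#'
#' @param dxy between-population divergence.
#' @param dx_out,dy_out divergence of each population to the outgroup over
#'   the same callable sites.
#' @return RND.
#' @export
rnd_window <- function(dxy, dx_out, dy_out) {
  denom <- (dx_out + dy_out) / 2
  out <- ifelse(is.na(denom) | denom <= 0, NA_real_, dxy / denom)
  if (any(!is.na(denom) & denom <= 0))
    warning("zero outgroup divergence; RND set to NA")
  out
}

#' Divergence of each population to the outgroup
#'
#' dXY between a population's haplotypes and the single outgroup sequence,
#' over the same site set and callable denominator used for the
#' between-population dXY.
#'
#' @param hap haploid matrix including ingroup rows only.
#' @param outgroup outgroup allele per site (0/1/NA).
#' @param pops factor per row.
#' @param pop population name.
#' @param n_callable callable sites.
#' @return per-site divergence to the outgroup.
#' @export
dxy_to_outgroup <- function(hap, outgroup, pops, pop, n_callable) {
  h <- hap[as.factor(pops) == pop, , drop = FALSE]
  sc <- site_counts(h)
  ok <- sc$n >= pmax(1, 0.5 * nrow(h)) & !is.na(outgroup)
  denom <- n_callable - sum(!ok)
  if (is.na(denom) || denom <= 0) return(NA_real_)
  p <- sc$i[ok] / sc$n[ok]
  og <- outgroup[ok]
  sum(ifelse(og == 1L, 1 - p, p)) / denom
}
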