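#' Pairwise genetic distance matrix
#'
#' 1 - identity-by-state over co-called sites: for each pair of samples,
#' the mean per-site allele-sharing distance `|g_i - g_j| / ploidy`
#' computed over sites called in both. The metric is configurable in
#' principle; this is the default used by the isolation-by-distance
#' analyses.
#'
#' @param gt samples x sites dosage matrix (0..ploidy, NA missing) or a
#'   `genotype_matrix`.
#' @param ploidy 2 for dosage genotypes, 1 for haploid 0/1 data.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
genetic_distance_matrix <- function(gt, ploidy = 2) {
  if (inherits(gt, "genotype_matrix")) gt <- gt$gt
  g <- as.matrix(gt) / ploidy
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    d[i, j] <- d[j, i] <-
      if (any(ok)) mean(abs(g[i, ok] - g[j, ok])) else NA_real_
  }
  d
}

#' Great-circle distance matrix in km
#'
#' Haversine distances on the WGS84 mean radius.
#'
#' @param lat,lon coordinate vectors in decimal degrees.
#' @return symmetric matrix of distances in km.
#' @export
geographic_distance_matrix <- function(lat, lon) {
  m <- geosphere::distm(cbind(lon, lat),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(names(lat), names(lat))
  m
}

#' Mantel test with row/column permutation
#'
#' Pearson correlation of the lower triangles of two symmetric matrices;
#' the null permutes rows and columns simultaneously (never individual
#' entries, which would break the within-row dependence). One-sided
#' `P = (#(null r >= observed r) + 1) / (n_perm + 1)`.
#'
#' @param genetic,geographic conformable symmetric matrices.
#' @param n_perm number of permutations (default 10,000).
#' @return list `(r, p_value, n_perm)`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 10000) {
  stopifnot(all(dim(genetic) == dim(geographic)))
  n <- nrow(genetic)
  lt <- lower.tri(genetic)
  gx <- genetic[lt]; gy <- geographic[lt]
  if (sd(gx) == 0 || sd(gy) == 0)
    stop("mantel_test: constant distance matrix")
  r <- cor(gx, gy)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    null[b] <- cor(genetic[p, p][lt], gy)
  }
  list(r = r, p_value = (sum(null >= r) + 1) / (n_perm + 1),
       n_perm = n_perm)
}

#' Binned weighted isolation-by-distance regression
#'
#' Genotype pairs are grouped into sequential 10-km bins
#' (\[0,10), \[10,20), ...); bins are used when their midpoint lies within
#' \[20, 120\] km and they hold at least 15 pairs. A linear regression of
#' mean genetic distance on bin midpoint is fitted with weights equal to
#' pair counts; the IBD strength is reported as
#' `ratio = slope / mean pairwise genetic distance over used bins`, with a
#' bootstrap standard error from resampling genotype pairs (re-binned per
#' replicate).
#'
#' @param genetic,geographic symmetric distance matrices (genetic unitless,
#'   geographic in km).
#' @param bin_width_km bin width (default 10).
#' @param midpoint_range_km inclusive midpoint range of usable bins
#'   (default c(20, 120)).
#' @param min_pairs minimum pairs per usable bin (default 15).
#' @param n_boot bootstrap replicates for the SE (default 1,000).
#' @return list `(slope, intercept, ratio, ratio_se, bins)` where `bins` is
#'   a data.frame (midpoint, mean_genetic, n_pairs, used).
#' @export
ibd_binned_regression <- function(genetic, geographic, bin_width_km = 10,
                                  midpoint_range_km = c(20, 120),
                                  min_pairs = 15, n_boot = 1000) {
  lt <- lower.tri(genetic)
  gd <- genetic[lt]; km <- geographic[lt]
  ok <- !is.na(gd) & !is.na(km)
  gd <- gd[ok]; km <- km[ok]
  fit_once <- function(gd, km) {
    bin <- floor(km / bin_width_km)
    mid <- (bin + 0.5) * bin_width_km
    tab <- data.frame(midpoint = tapply(mid, bin, min),
                      mean_genetic = tapply(gd, bin, mean),
                      n_pairs = as.integer(table(bin)))
    tab$used <- tab$n_pairs >= min_pairs &
      tab$midpoint >= midpoint_range_km[1] &
      tab$midpoint <= midpoint_range_km[2]
    u <- tab[tab$used, ]
    if (nrow(u) < 3) return(NULL)
    fit <- lm(mean_genetic ~ midpoint, data = u, weights = u$n_pairs)
    list(slope = coef(fit)[["midpoint"]],
         intercept = coef(fit)[["(Intercept)"]],
         ratio = coef(fit)[["midpoint"]] / mean(u$mean_genetic),
         bins = tab)
  }
  main <- fit_once(gd, km)
  if (is.null(main))
    stop(sprintf(paste0("fewer than 3 usable bins (need midpoint in ",
                        "[%g, %g] km and >= %d pairs per bin)"),
                 midpoint_range_km[1], midpoint_range_km[2], min_pairs))
  boots <- numeric(0)
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(gd), replace = TRUE)
      r <- fit_once(gd[idx], km[idx])
      if (is.null(r)) NA_real_ else r$ratio
    }, numeric(1))
  }
  list(slope = main$slope, intercept = main$intercept, ratio = main$ratio,
       ratio_se = if (length(boots)) sd(boots, na.rm = TRUE) else NA_real_,
       bins = main$bins)
}
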