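#' Simulate neutral null distributions of pi and FST
#'
#' Simulates `n_segments` independent 20-kb segments under the demographic
#' model at each recombination level of the grid, and computes per-segment
#' pi per group and Weir-Cockerham FST per group pair with this package's
#' own estimators on the simulated haplotypes.
#'
#' @param model a `demographic_model`.
#' @param n_segments segments per recombination level (the study-scale
#'   default is 100,000; smaller values are appropriate interactively).
#' @param recombination_grid recombination levels in cM/Mb (default the
#'   eight-level grid 0, 1, 5, 10, 30, 50, 100, 250).
#' @param window_length_bp segment length (default 20,000).
#' @param seed integer seed.
#' @return object of class `null_distribution`: named list (one element per
#'   recombination level) of data.frames with columns `pi_<group>` and
#'   `fst_<pop1>_<pop2>`.
#' @export
simulate_null <- function(model, n_segments,
                          recombination_grid = c(0, 1, 5, 10, 30, 50, 100, 250),
                          window_length_bp = 20000L, seed = NULL) {
  validate_demographic_model(model)
  if (any(recombination_grid < 0)) stop("invalid recombination level")
  if (!is.null(seed)) set.seed(seed)
  pn <- as.character(model$populations$name)
  pairs <- if (length(pn) > 1) combn(pn, 2) else NULL
  out <- list()
  for (r in recombination_grid) {
    if (n_segments == 0) {
      out[[as.character(r)]] <- data.frame()
      next
    }
    cfg <- simulation_config(n_windows = n_segments,
                             window_length_bp = window_length_bp,
                             recombination_cM_per_Mb = r, seed = NULL)
    sims <- simulate_windows(model, cfg)
    stats <- window_stats_from_sims(sims)
    out[[as.character(r)]] <- stats
  }
  structure(list(levels = out, grid = recombination_grid,
                 n_segments = n_segments, model = model),
            class = "null_distribution")
}

# per-window pi per group and fst/dxy per pair straight from haplotypes
window_stats_from_sims <- function(sims) {
  pn <- levels(sims$sample_pops)
  L <- sims$config$window_length_bp
  pairs <- if (length(pn) > 1) combn(pn, 2) else NULL
  rows <- lapply(sims$windows, function(win) {
    hap <- win$hap
    row <- list()
    for (p in pn) {
      h <- hap[sims$sample_pops == p, , drop = FALSE]
      row[[paste0("pi_", p)]] <- window_pi(h, L)
    }
    if (!is.null(pairs)) for (j in seq_len(ncol(pairs))) {
      pr <- pairs[, j]
      f <- wc_fst_window(hap, sims$sample_pops, pair = pr, ploidy = 1)
      row[[paste0("fst_", pr[1], "_", pr[2])]] <- f$fst
      row[[paste0("dxy_", pr[1], "_", pr[2])]] <-
        dxy_window(hap, sims$sample_pops, pair = pr, n_callable = L)
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U with normal approximation and tie correction;
#' exact enumeration of all allocations when both samples have at most 8
#' observations. `U` is the number of (x, y) pairs with x > y (+ half the
#' ties), so `U = n1 * n2` when every x exceeds every y.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list `(U, p_value, method)`.
#' @export
mann_whitney_compare <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    # exact enumeration over all C(n1+n2, n1) allocations of the ranks
    idx <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Goodness of fit of an observed SFS to a demographic model
#'
#' Simulates the model, builds the expected (mean) per-population SFS at
#' the observed projection sizes, and reports per-entry residuals, a
#' multinomial log-likelihood of the observed counts given the expected
#' proportions, and a comparison of summary statistics (mean pi per group,
#' mean FST per pair) between observed input and simulation.
#'
#' @param model a `demographic_model`.
#' @param observed an `sfs` object (projected to the model's sample sizes).
#' @param n_loci number of simulated 20-kb loci used to build the
#'   expectation (default 200).
#' @param seed integer seed.
#' @param observed_stats optional named list of observed summary statistics
#'   to report next to the simulated ones.
#' @return list with `expected` (per-pop counts scaled to the observed
#'   totals), `residuals`, `log_likelihood`, `summary_stats`.
#' @export
sfs_goodness_of_fit <- function(model, observed, n_loci = 200, seed = NULL,
                                observed_stats = NULL) {
  stopifnot(inherits(observed, "sfs"))
  if (observed$n_sites_used == 0) stop("observed SFS contains no sites")
  if (!is.null(seed)) set.seed(seed)
  pn <- as.character(model$populations$name)
  if (!setequal(names(observed$spectra), pn))
    stop("SFS populations do not match the model")
  targets <- observed$targets
  n_hap <- 2L * model$populations$n_diploid
  if (any(targets[pn] > n_hap))
    stop("projection sizes exceed the model's sampled haplotypes")
  cfg <- simulation_config(n_windows = n_loci, recombination_cM_per_Mb = 0,
                           seed = NULL)
  sims <- simulate_windows(model, cfg)
  fold <- observed$orientation == "folded"
  agg <- NULL
  for (w in seq_along(sims$windows)) {
    s <- downsampled_sfs(sims$windows[[w]]$hap, sims$sample_pops,
                         targets = targets, fold = fold)
    if (is.null(agg)) agg <- s$spectra
    else for (p in pn) agg[[p]] <- agg[[p]] + s$spectra[[p]]
  }
  expected <- list(); resid <- list(); ll <- 0
  for (p in pn) {
    obs <- observed$spectra[[p]]
    if (length(obs) != length(agg[[p]]))
      stop(sprintf("SFS dimension mismatch for population %s", p))
    prop <- (agg[[p]] + 0.5) / sum(agg[[p]] + 0.5)  # light smoothing
    expected[[p]] <- prop * sum(obs)
    resid[[p]] <- obs - expected[[p]]
    ll <- ll + sum(obs * log(prop))
  }
  stats <- window_stats_from_sims(sims)
  list(expected = expected, residuals = resid, log_likelihood = ll,
       summary_stats = list(simulated = colMeans(stats, na.rm = TRUE),
                            observed = observed_stats))
}

#' Moment estimate of Ne from Watterson's theta
#'
#' `Ne = thetaW / (4 mu)` with `thetaW` per site and `mu` per site per
#' generation.
#'
#' @param theta_w per-site Watterson's theta.
#' @param mu_per_generation mutation rate per site per generation.
#' @return estimated diploid effective size.
#' @export
estimate_ne_watterson <- function(theta_w, mu_per_generation) {
  if (mu_per_generation <= 0) stop("mutation rate must be > 0")
  if (any(theta_w < 0, na.rm = TRUE)) stop("theta_w must be >= 0")
  theta_w / (4 * mu_per_generation)
}

#' Moment estimate of split time from net divergence
#'
#' `T = da / (2 mu_year)` in years: under clean isolation the expected net
#' divergence is `2 mu T`.
#'
#' @param da per-site net divergence.
#' @param mu_per_year mutation rate per site per year.
#' @return estimated split time in years.
#' @export
estimate_split_time_da <- function(da, mu_per_year) {
  if (mu_per_year <= 0) stop("mutation rate must be > 0")
  if (any(da < 0, na.rm = TRUE)) stop("da must be >= 0")
  da / (2 * mu_per_year)
}
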