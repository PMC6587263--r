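#' Z-transform a per-window statistic
#'
#' `Z = (x - mean) / sd` over the finite values; missing windows are
#' excluded from the mean and sd and stay missing. Applied separately per
#' group (pi) or per group pair (FST) by the caller. The default uses the
#' population (denominator n) standard deviation; `sd_type = "sample"`
#' switches to n - 1.
#'
#' @param x numeric vector of per-window values.
#' @param sd_type `"population"` (n) or `"sample"` (n - 1).
#' @return Z scores, same length as `x`.
#' @export
z_transform <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("z_transform needs at least 2 finite values")
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (sd_type == "population") s <- s * sqrt((sum(ok) - 1) / sum(ok))
  if (s == 0) stop("z_transform: zero standard deviation")
  out <- rep(NA_real_, length(x))
  out[ok] <- (x[ok] - m) / s
  out
}

#' Call outlier islands from Z scores
#'
#' Windows with `Z >= threshold` are flagged (the threshold is inclusive).
#' Returns both the individual flagged windows and runs of adjacent flagged
#' windows collapsed per chromosome.
#'
#' @param windows data.frame (chrom, start, end) of all windows, in order.
#' @param z Z score per window.
#' @param threshold inclusive threshold (default 2).
#' @return object of class `region_set` with `windows` (flagged rows with
#'   window ids and z) and `runs` (adjacent flagged windows merged).
#' @export
call_islands <- function(windows, z, threshold = 2) {
  flag <- !is.na(z) & z >= threshold
  ids <- which(flag)
  win <- windows[ids, , drop = FALSE]
  if (is.null(win$window)) win$window <- ids
  win$z <- z[ids]
  runs <- merge_intervals(win, max_gap = 0)
  structure(list(windows = win, runs = runs, kind = "island",
                 threshold = threshold), class = "region_set")
}

#' Windows flagged in every group
#'
#' @param island_sets list (one per group) of `region_set` objects or
#'   integer window-id vectors.
#' @return integer ids of windows flagged in all groups.
#' @export
shared_islands <- function(island_sets) {
  if (length(island_sets) < 2) stop("shared_islands needs at least 2 groups")
  ids <- lapply(island_sets, function(s)
    if (inherits(s, "region_set")) s$windows$window else as.integer(s))
  Reduce(intersect, ids)
}

# merge 0-based half-open intervals on the same chrom when gap < max_gap;
# max_gap = 0 merges only touching/adjacent intervals
merge_intervals <- function(df, max_gap) {
  if (!nrow(df)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0)))
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max(max_gap, 1L),
                               with.revmap = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             n_windows = lengths(red$revmap))
}

#' Merge islands separated by small gaps into regions
#'
#' Islands on the same chromosome whose gap is strictly less than
#' `max_gap` (default 1.5 Mb) are merged into single segments spanning from
#' the first start to the last end. Idempotent and order-independent.
#'
#' @param islands a `region_set` or a data.frame (chrom, start, end).
#' @param max_gap maximum gap in bp (strict `<`; default 1,500,000).
#' @return `region_set` of merged regions.
#' @export
merge_regions <- function(islands, max_gap = 1500000) {
  df <- if (inherits(islands, "region_set")) islands$windows else islands
  merged <- merge_intervals(df, max_gap = max_gap)
  structure(list(windows = df, runs = merged, kind = "merged",
                 max_gap = max_gap), class = "region_set")
}

#' Drop windows overlapping a mask
#'
#' Any overlap with a mask interval excludes the window (used to remove
#' regions under long-term balancing selection before the FST screen).
#'
#' @param windows data.frame (chrom, start, end, ...).
#' @param mask `region_set` or data.frame (chrom, start, end); empty mask
#'   returns the input unchanged.
#' @return the filtered data.frame.
#' @export
exclude_regions <- function(windows, mask) {
  mdf <- if (inherits(mask, "region_set")) mask$runs else mask
  if (is.null(mdf) || !nrow(mdf)) return(windows)
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  mgr <- GenomicRanges::GRanges(mdf$chrom,
                                IRanges::IRanges(mdf$start + 1L, mdf$end))
  hit <- IRanges::overlapsAny(wgr, mgr)
  windows[!hit, , drop = FALSE]
}

#' Randomization test of islands against the genomic background
#'
#' Observed difference = mean(statistic in islands) - mean(statistic in
#' background). The null redraws `|islands|` windows without replacement
#' from all windows `n_perm` times; two-sided
#' `P = (#(|null| >= |observed|) + 1) / (n_perm + 1)`, so the smallest
#' attainable P with the default 100,000 permutations is just under 1e-5.
#'
#' @param values per-window statistic (islands and background together).
#' @param is_island logical per window.
#' @param n_perm number of permutations (default 100,000).
#' @return list `(observed, p_value, n_perm)`.
#' @export
randomization_test <- function(values, is_island, n_perm = 100000) {
  stopifnot(length(values) == length(is_island))
  ok <- !is.na(values)
  values <- values[ok]; is_island <- is_island[ok]
  k <- sum(is_island)
  n <- length(values)
  if (k == 0 || k == n)
    stop("islands must be a non-empty strict subset of the windows")
  obs <- mean(values[is_island]) - mean(values[!is_island])
  tot <- sum(values)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sum(values[sample.int(n, k)])
    null[b] <- s / k - (tot - s) / (n - k)
  }
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = n_perm)
}

#' Compare scaled recombination between region classes
#'
#' Scales the population recombination rate by diversity (`rho / pi`,
#' missing where `pi = 0`), reports class means, a one-way F test across
#' classes, and per-class randomization tests against the background class
#' with Bonferroni correction.
#'
#' @param rho per-window population-scaled recombination rate (input, e.g.
#'   from an external LD-based estimator).
#' @param pi per-window diversity.
#' @param classes factor per window; the level named by `background` is the
#'   reference.
#' @param background name of the background level (default `"background"`).
#' @param n_perm randomization permutations (default 10,000).
#' @param n_comparisons Bonferroni family size (default: number of
#'   non-background classes).
#' @return list with `means`, `f_statistic`, `df`, `p_f`, and a data.frame
#'   `randomization` (class, observed, p_raw, p_bonferroni).
#' @export
scaled_recombination_compare <- function(rho, pi, classes,
                                         background = "background",
                                         n_perm = 10000,
                                         n_comparisons = NULL) {
  classes <- as.factor(classes)
  rp <- ifelse(!is.na(pi) & pi > 0, rho / pi, NA_real_)
  ok <- !is.na(rp)
  if (any(table(classes[ok]) < 2))
    stop("every class needs at least 2 windows with defined rho/pi")
  fit <- lm(rp[ok] ~ classes[ok])
  an <- anova(fit)
  cls <- setdiff(levels(classes), background)
  if (is.null(n_comparisons)) n_comparisons <- length(cls)
  rt <- lapply(cls, function(cl) {
    sel <- ok & (classes == cl | classes == background)
    r <- randomization_test(rp[sel], classes[sel] == cl, n_perm = n_perm)
    data.frame(class = cl, observed = r$observed, p_raw = r$p_value,
               p_bonferroni = min(1, r$p_value * n_comparisons))
  })
  list(means = tapply(rp[ok], classes[ok], mean),
       f_statistic = an$`F value`[1], df = an$Df,
       p_f = an$`Pr(>F)`[1],
       randomization = do.call(rbind, rt))
}

#' Island effect adjusted for recombination and gene density
#'
#' Fits `statistic ~ island + rho/pi + gene_density` by least squares and
#' reports the island-term F statistic, its P value and the effect
#' direction, so elevated diversity in islands can be tested while
#' controlling for both covariates.
#'
#' @param statistic per-window response.
#' @param island logical per window.
#' @param rho_pi,gene_density covariates.
#' @return list `(effect, f_statistic, p_value, direction, n)`.
#' @export
adjusted_island_test <- function(statistic, island, rho_pi, gene_density) {
  df <- data.frame(y = statistic, island = as.logical(island),
                   rho_pi = rho_pi, gd = gene_density)
  df <- df[complete.cases(df), ]
  if (nrow(df) < 10) stop("adjusted_island_test needs >= 10 complete cases")
  if (sd(df$rho_pi) == 0 || sd(df$gd) == 0 ||
      abs(cor(df$rho_pi, df$gd)) > 0.9999)
    stop("collinear covariates")
  fit <- lm(y ~ island + rho_pi + gd, data = df)
  an <- anova(fit)
  eff <- coef(fit)[["islandTRUE"]]
  list(effect = eff,
       f_statistic = an["island", "F value"],
       p_value = an["island", "Pr(>F)"],
       direction = sign(eff), n = nrow(df))
}
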