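test_that("z_transform uses the fixed sd convention and is affine-invariant", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(z[3], 1.2247, tolerance = 1e-4)   # population sd
  expect_equal(mean(z), 0, tolerance = 1e-9)
  x <- rnorm(50)
  expect_equal(z_transform(x), z_transform(x + 100))
  expect_equal(z_transform(x), z_transform(3 * x + 7))
  zs <- z_transform(c(1, 2, 3), sd_type = "sample")
  expect_equal(zs[3], 1, tolerance = 1e-9)
  # missing windows are excluded but keep their slots
  z2 <- z_transform(c(1, NA, 2, 3))
  expect_true(is.na(z2[2]))
  expect_equal(z2[-2], z_transform(c(1, 2, 3)))
  expect_error(z_transform(c(1, NA)), "2 finite")
  expect_error(z_transform(c(2, 2, 2)), "zero standard deviation")
})

test_that("the Gaussian Z >= 2 tail matches its nominal mass", {
  set.seed(303)
  x <- rnorm(100000)
  z <- z_transform(x)
  frac <- mean(z >= 2)
  p <- pnorm(2, lower.tail = FALSE)
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("island calling applies an inclusive threshold", {
  win <- data.frame(chrom = "chr1", start = (0:4) * 20000,
                    end = (1:5) * 20000)
  z <- c(1.9, 2.0, 2.5, -1, NA)
  isl <- call_islands(win, z)
  expect_equal(isl$windows$window, c(2L, 3L))
  expect_equal(isl$runs$n_windows, 2L)       # adjacent windows form a run
  expect_equal(nrow(call_islands(win, rep(0, 5))$windows), 0L)
})

test_that("shared islands intersect across all groups", {
  expect_equal(shared_islands(list(c(1, 2, 3), c(2, 3, 4), c(3, 2))),
               c(2, 3))
  expect_equal(shared_islands(list(c(1, 5), c(1, 5))), c(1, 5))
  # flagged in 3 of 4 groups is not shared
  expect_equal(length(shared_islands(list(1, 1, 1, 2))), 0L)
  expect_error(shared_islands(list(1)), "at least 2")
  # independent island draws intersect at about the product density
  set.seed(9)
  p <- 0.3; n <- 4000
  sets <- lapply(1:4, function(i) which(runif(n) < p))
  dens <- length(shared_islands(sets)) / n
  se <- sqrt(p^4 * (1 - p^4) / n)
  expect_lt(abs(dens - p^4), 3 * se)
})

test_that("region merging respects the strict 1.5 Mb gap rule", {
  isl <- data.frame(chrom = "chr1", start = c(100000, 1500000),
                    end = c(120000, 1520000))
  m <- merge_regions(isl)        # gap 1,380,000 < 1.5 Mb
  expect_equal(nrow(m$runs), 1L)
  expect_equal(m$runs$start, 100000)
  expect_equal(m$runs$end, 1520000)
  isl2 <- data.frame(chrom = "chr1", start = c(0, 1520000),
                     end = c(20000, 1540000))   # gap exactly 1.5 Mb
  expect_equal(nrow(merge_regions(isl2)$runs), 2L)
  isl3 <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                     end = c(20000, 20000))
  expect_equal(nrow(merge_regions(isl3)$runs), 2L)
  # idempotent and order-independent
  m2 <- merge_regions(m$runs[, c("chrom", "start", "end")])
  expect_equal(m2$runs[, 1:3], m$runs[, 1:3])
  shuffled <- isl[c(2, 1), ]
  expect_equal(merge_regions(shuffled)$runs[, 1:3], m$runs[, 1:3])
})

test_that("exclusion drops any overlapping window", {
  win <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(0, 20000, 0), end = c(20000, 40000, 20000))
  expect_equal(exclude_regions(win, data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0))), win)
  mask <- data.frame(chrom = "chr1", start = 30000, end = 50000)
  out <- exclude_regions(win, mask)   # half-overlap excludes
  expect_equal(nrow(out), 2L)
  expect_false(any(out$chrom == "chr1" & out$start == 20000))
  mask2 <- data.frame(chrom = "chr2", start = 0, end = 1e6)
  expect_false(any(exclude_regions(win, mask2)$chrom == "chr2"))
})

test_that("randomization test is extreme-safe and calibrated", {
  vals <- c(sort(rnorm(100)), 10, 11, 12)
  isl <- c(rep(FALSE, 100), TRUE, TRUE, TRUE)
  # islands chosen as the top windows of the same statistic: minimal P
  r <- randomization_test(vals, isl, n_perm = 999)
  expect_equal(r$p_value, 1 / 1000)
  expect_error(randomization_test(vals, rep(TRUE, 103), 10), "strict subset")
  # null calibration at reduced permutation count
  set.seed(77)
  ps <- replicate(120, {
    v <- rnorm(60)
    i <- seq_len(60) %in% sample(60, 8)
    randomization_test(v, i, n_perm = 199)$p_value
  })
  # discrete P values tie under KS; the calibration signal still shows
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("scaled recombination comparisons control the family error", {
  set.seed(15)
  n <- 160
  classes <- factor(rep(c("r1", "r2", "r3", "background"), each = n / 4),
                    levels = c("background", "r1", "r2", "r3"))
  rho <- rnorm(n, 10); pi <- rep(1, n)
  res <- scaled_recombination_compare(rho, pi, classes, n_perm = 499)
  expect_equal(res$df[1], 3)                     # 3 regions + background
  expect_gt(res$p_f, 0.001)
  # one class shifted by 5 sd is detected
  rho2 <- rho; rho2[classes == "r2"] <- rho2[classes == "r2"] + 5
  res2 <- scaled_recombination_compare(rho2, pi, classes, n_perm = 1999)
  expect_lt(res2$p_f, 0.001)
  expect_lt(res2$randomization$p_bonferroni[2], 0.01)
  # Bonferroni arithmetic with an explicit family of 12
  res3 <- scaled_recombination_compare(rho2, pi, classes, n_perm = 499,
                                       n_comparisons = 12)
  expect_equal(res3$randomization$p_bonferroni,
               pmin(1, res3$randomization$p_raw * 12))
  expect_error(scaled_recombination_compare(rho[1:5], pi[1:5],
                                            factor(c("a", "b", "b", "b", "b")),
                                            background = "b"),
               "at least 2")
})

test_that("the covariate-adjusted island test recovers injected effects", {
  set.seed(19)
  n <- 300
  island <- seq_len(n) <= 40
  rho_pi <- rnorm(n); gd <- rnorm(n)
  y <- 0.5 * rho_pi + 0.2 * gd + 2 * island + rnorm(n)
  r <- adjusted_island_test(y, island, rho_pi, gd)
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$direction, 1)
  # covariate fully explaining the statistic leaves no island effect
  y2 <- 3 * rho_pi + rnorm(n, sd = 0.1)
  r2 <- adjusted_island_test(y2, island, rho_pi, gd)
  expect_lt(abs(r2$effect), 0.1)
  expect_error(adjusted_island_test(y, island, rho_pi, rho_pi), "collinear")
  # null calibration over replicates
  ps <- replicate(60, {
    yy <- rnorm(80)
    adjusted_island_test(yy, seq_len(80) <= 10, rnorm(80), rnorm(80))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
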