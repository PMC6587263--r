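test_that("mantel_test matches an independent oracle and vegan", {
  A <- sym(6, 1); B <- A + sym(6, 2) * 0.3
  set.seed(10)
  r <- mantel_test(A, B, n_perm = 999)
  o <- oracle_mantel(A, B, n_perm = 999, seed = 10)
  expect_equal(r$r, o$r, tolerance = 1e-12)
  expect_equal(r$p_value, o$p, tolerance = 1e-12)
  if (requireNamespace("vegan", quietly = TRUE)) {
    v <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
    expect_equal(r$r, unname(v$statistic), tolerance = 1e-12)
  }
  # identical matrices: r = 1 at the minimal attainable P
  set.seed(3)
  ri <- mantel_test(A, A, n_perm = 199)
  expect_equal(ri$r, 1)
  expect_equal(ri$p_value, 1 / 200)
  expect_error(mantel_test(matrix(1, 4, 4), A[1:4, 1:4]), "constant")
})

test_that("mantel_test is invariant to joint relabeling and calibrated", {
  A <- sym(8, 4); B <- sym(8, 5)
  p <- sample(8)
  set.seed(6); r1 <- mantel_test(A, B, n_perm = 299)
  set.seed(6); r2 <- mantel_test(A[p, p], B[p, p], n_perm = 299)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  set.seed(7)
  ps <- replicate(150, mantel_test(sym(7, sample.int(1e6, 1)),
                                   sym(7, sample.int(1e6, 1)),
                                   n_perm = 199)$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("IBD binned regression recovers a linear signal", {
  set.seed(12)
  n <- 60
  km_pos <- runif(n, 0, 120)
  geo <- abs(outer(km_pos, km_pos, "-"))
  b <- 2e-5
  gen <- 0.01 + b * geo + sym(n, 13) * 0.001
  diag(gen) <- 0
  r <- ibd_binned_regression(gen, geo, n_boot = 200)
  expect_lt(abs(r$slope - b), 3 * r$ratio_se * mean(r$bins$mean_genetic[r$bins$used]) + 0.5 * b)
  expect_true(all(r$bins$n_pairs[r$bins$used] >= 15))
  expect_true(all(r$bins$midpoint[r$bins$used] >= 20 &
                    r$bins$midpoint[r$bins$used] <= 120))
  # all pairs within 15 km: no usable bins
  geo2 <- geo / 10
  expect_error(ibd_binned_regression(gen, geo2, n_boot = 0), "usable bins")
  # weighted regression with equal weights equals OLS
  u <- r$bins[r$bins$used, ]
  w_eq <- lm(mean_genetic ~ midpoint, data = u, weights = rep(1, nrow(u)))
  ols <- lm(mean_genetic ~ midpoint, data = u)
  expect_equal(coef(w_eq), coef(ols), tolerance = 1e-12)
})

test_that("stepping-stone geography produces isolation by distance", {
  # 4 demes on a line, nearest-neighbor migration only
  mig <- matrix(0, 4, 4)
  for (i in 1:3) mig[i, i + 1] <- mig[i + 1, i] <- 2e-5
  model <- demographic_model(
    populations = data.frame(name = paste0("P", 1:4), n_diploid = 4),
    epochs = setNames(lapply(1:4, function(i)
      data.frame(start_gen = 0, ne = 5000)), paste0("P", 1:4)),
    splits = data.frame(time_gen = c(50000, 50000, 50000),
                        derived = c("P2", "P3", "P4"),
                        ancestral = c("P1", "P1", "P1")),
    migration = mig)
  hits <- 0; reps <- 10
  for (rr in seq_len(reps)) {
    cfg <- simulation_config(n_windows = 40, recombination_cM_per_Mb = 0,
                             seed = 100 + rr)
    sims <- simulate_windows(model, cfg)
    hap <- do.call(cbind, lapply(sims$windows, `[[`, "hap"))
    gen <- genetic_distance_matrix(hap, ploidy = 1)
    samples <- data.frame(sample = seq_len(nrow(hap)),
                          group = sims$sample_pops)
    anchors <- data.frame(group = paste0("P", 1:4), lat = 45,
                          lon = -114 + (0:3) * 0.6)
    geo <- assign_geography(samples, anchors, spacing_km = 0.1)
    gm <- geographic_distance_matrix(geo$lat, geo$lon)
    if (mantel_test(gen, gm, n_perm = 199)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("ld_r2 respects MAF and distance bounds", {
  set.seed(31)
  g <- matrix(rbinom(40 * 3, 2, 0.4), 40, 3)
  g[, 2] <- g[, 1]                       # duplicated SNP
  pos <- c(100, 200, 50301)
  tab <- ld_r2(g, chrom = rep("c", 3), pos = pos, max_dist = 50000)
  expect_equal(tab$r2[tab$pos1 == 100 & tab$pos2 == 200], 1)
  # 50,001 bp apart is excluded
  expect_false(any(tab$pos1 == 200 & tab$pos2 == 50301))
  expect_true(any(tab$pos1 == 100 & tab$pos2 == 200))
  # rare SNPs are dropped before pairing
  g2 <- cbind(g[, 1], c(rep(0, 39), 1))
  tab2 <- ld_r2(g2, chrom = rep("c", 2), pos = c(1, 2))
  expect_equal(nrow(tab2), 0L)
  # r2 symmetric under allele-label swap
  tab3 <- ld_r2(2 - g, chrom = rep("c", 3), pos = pos)
  expect_equal(tab$r2, tab3$r2, tolerance = 1e-12)
})

test_that("independent SNPs have mean r2 near 1/n", {
  set.seed(41)
  n <- 50
  g <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  tab <- ld_r2(g, chrom = rep("c", 60), pos = seq_len(60))
  se <- sd(tab$r2) / sqrt(nrow(tab))
  # pairs share SNPs so the SE underestimates; allow a wide band
  expect_lt(abs(mean(tab$r2) - 1 / n), 6 * se + 0.005)
})

test_that("Hill-Weir fit recovers the generating rho", {
  set.seed(51)
  d <- sort(sample(100:50000, 400))
  rho <- 1e-3; n <- 40
  r2 <- hill_weir_expectation(rho * d, n) + rnorm(400, 0, 0.01)
  fit <- hill_weir_fit(data.frame(dist = d, r2 = r2), n = n)
  expect_lt(abs(fit$rho - rho) / rho, 0.10)
  expect_true(is.finite(fit$half_decay_bp))
  # half-decay shrinks as rho grows
  r2b <- hill_weir_expectation(5e-3 * d, n) + rnorm(400, 0, 0.01)
  fitb <- hill_weir_fit(data.frame(dist = d, r2 = r2b), n = n)
  expect_lt(fitb$half_decay_bp, fit$half_decay_bp)
  # flat r2: rho collapses to the zero boundary
  flat <- hill_weir_fit(data.frame(dist = d,
                                   r2 = hill_weir_expectation(0, n) +
                                     rnorm(400, 0, 0.001)), n = n)
  expect_lt(flat$rho, 1e-6)
})

test_that("LD decay steepens with simulated recombination", {
  model <- single_pop_model(ne = 10000, n_diploid = 20)
  half_at <- function(r, seed) {
    cfg <- simulation_config(n_windows = 30, recombination_cM_per_Mb = r,
                             seed = seed)
    sims <- simulate_windows(model, cfg)
    tabs <- lapply(seq_along(sims$windows), function(i) {
      w <- sims$windows[[i]]
      ld_r2(w$hap, chrom = rep(i, length(w$pos)), pos = w$pos)
    })
    tab <- do.call(rbind, tabs)
    hill_weir_fit(tab, n = 40)$half_decay_bp
  }
  h <- c(half_at(5, 61), half_at(30, 62), half_at(120, 63))
  expect_true(all(diff(h) < 0))
})

test_that("LD pruning leaves no correlated pair behind", {
  set.seed(71)
  n <- 60
  base <- matrix(rbinom(n * 30, 2, 0.5), n, 30)
  # duplicate some columns to create perfect LD
  g <- cbind(base, base[, 1:5])
  pos <- seq_len(ncol(g))
  ord <- order(pos)
  kept <- ld_prune(g, pos)
  # two identical adjacent SNPs: exactly one survives
  g2 <- base[, c(1, 1)]
  expect_equal(length(ld_prune(g2, c(1, 2))), 1L)
  # independent SNPs survive untouched
  set.seed(72)
  g3 <- matrix(rbinom(500 * 10, 2, 0.5), 500, 10)
  expect_equal(ld_prune(g3, 1:10), 1:10)
  # postcondition audit: no within-window kept pair above the threshold
  for (a in seq_along(kept)) for (b in seq_along(kept)) {
    if (b <= a || b - a >= 50) next
    r <- cor(g[, kept[a]], g[, kept[b]])
    expect_lte(r^2, 0.2 + 1e-12)
  }
})
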