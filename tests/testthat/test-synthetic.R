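test_that("demographic model validation names the offending component", {
  expect_error(single_pop_model(ne = -5), "non-positive Ne")
  expect_error(demographic_model(
    populations = data.frame(name = c("A", "B"), n_diploid = 5),
    epochs = list(A = data.frame(start_gen = 0, ne = 100),
                  B = data.frame(start_gen = 0, ne = 100)),
    splits = data.frame(time_gen = 0, derived = "B", ancestral = "A")),
    "non-positive time")
  expect_error(demographic_model(
    populations = data.frame(name = c("A", "B"), n_diploid = 5),
    epochs = list(A = data.frame(start_gen = 0, ne = 100),
                  B = data.frame(start_gen = c(0, 2000), ne = 100)),
    splits = data.frame(time_gen = 1000, derived = "B", ancestral = "A")),
    "after its split")
  expect_error(demographic_model(
    populations = data.frame(name = c("A", "B"), n_diploid = 5),
    epochs = list(A = data.frame(start_gen = 0, ne = 100),
                  B = data.frame(start_gen = 0, ne = 100))),
    "never coalesce")
  expect_error(demographic_model(
    populations = data.frame(name = "A", n_diploid = 5),
    epochs = list(A = data.frame(start_gen = 0, ne = 100)),
    mu_per_site_per_year = 0), "mu")
})

test_that("neutral single-population windows match 4 Ne mu", {
  model <- single_pop_model(ne = 10000, n_diploid = 10)
  cfg <- simulation_config(n_windows = 1000, recombination_cM_per_Mb = 0,
                           seed = 101)
  sims <- simulate_windows(model, cfg)
  pis <- vapply(sims$windows, function(w) window_pi(w$hap, 20000), numeric(1))
  thetas <- vapply(sims$windows, function(w)
    window_theta_d(w$hap, 20000)$theta_w, numeric(1))
  ds <- vapply(sims$windows, function(w)
    window_theta_d(w$hap, 20000)$tajima_d, numeric(1))
  expected <- 4 * 10000 * 1.4e-8
  expect_lt(abs(mean(pis) - expected), 3 * sd(pis) / sqrt(length(pis)))
  expect_lt(abs(mean(thetas) - expected),
            3 * sd(thetas) / sqrt(length(thetas)))
  # Tajima's D centers near zero (it carries a small negative
  # finite-sample bias, so the check is an absolute band)
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})

test_that("two populations with an immediate split show no differentiation", {
  model <- two_pop_isolation(ne = 10000, split_gen = 1, n_diploid = 10)
  cfg <- simulation_config(n_windows = 300, recombination_cM_per_Mb = 0,
                           seed = 7)
  sims <- simulate_windows(model, cfg)
  fst <- vapply(sims$windows, function(w)
    wc_fst_window(w$hap, sims$sample_pops, ploidy = 1)$fst, numeric(1))
  expect_lt(abs(mean(fst, na.rm = TRUE)), 3 * sd(fst, na.rm = TRUE) /
              sqrt(sum(!is.na(fst))))
})

test_that("recombination reduces the inter-window variance of pi", {
  model <- single_pop_model(ne = 10000, n_diploid = 10)
  pi_at <- function(r, seed) {
    cfg <- simulation_config(n_windows = 500, recombination_cM_per_Mb = r,
                             seed = seed)
    vapply(simulate_windows(model, cfg)$windows,
           function(w) window_pi(w$hap, 20000), numeric(1))
  }
  p0 <- pi_at(0, 31); p250 <- pi_at(250, 32)
  expect_lt(var(p250), var(p0))
  # means unchanged
  expect_lt(abs(mean(p250) - mean(p0)),
            3 * sqrt(var(p0) / 500 + var(p250) / 500))
})

test_that("a fixed seed reproduces the simulation exactly", {
  model <- default_demography(4)
  cfg <- simulation_config(n_windows = 5, seed = 99,
                           signal_specs = list(signal_spec("balanced", 2)))
  s1 <- simulate_windows(model, cfg)
  s2 <- simulate_windows(model, cfg)
  expect_identical(s1$windows, s2$windows)
})

test_that("balanced signals double diversity without raising FST", {
  model <- default_demography(10)
  n_sig <- 50
  cfg <- simulation_config(n_windows = 2 * n_sig,
                           recombination_cM_per_Mb = 0, seed = 55,
                           signal_specs = list(
                             signal_spec("balanced", windows = 1:n_sig,
                                         tmrca_generations = 5e5)))
  sims <- simulate_windows(model, cfg)
  st <- popgenscan:::window_stats_from_sims(sims)
  sig <- seq_len(n_sig); bg <- n_sig + seq_len(n_sig)
  for (p in c("WES", "COL", "UTA", "NOR")) {
    col <- paste0("pi_", p)
    expect_gt(mean(st[[col]][sig]), 2 * median(st[[col]][bg]))
  }
  # FST not elevated in signal windows
  expect_lt(mean(st$fst_WES_NOR[sig], na.rm = TRUE),
            mean(st$fst_WES_NOR[bg], na.rm = TRUE) + 0.05)
  # Tajima's D elevated
  tds <- function(rows) mean(vapply(sims$windows[rows], function(w) {
    h <- w$hap[sims$sample_pops == "WES", , drop = FALSE]
    window_theta_d(h, 20000)$tajima_d
  }, numeric(1)), na.rm = TRUE)
  expect_gt(tds(sig), tds(bg))
})

test_that("sorted signals fix deep haplogroups between groups", {
  model <- two_pop_isolation(ne = 10000, split_gen = 20000, n_diploid = 10)
  cfg <- simulation_config(n_windows = 30, recombination_cM_per_Mb = 0,
                           seed = 56,
                           signal_specs = list(
                             signal_spec("sorted", windows = 1:15,
                                         freq_A = c(X = 1, Y = 0))))
  sims <- simulate_windows(model, cfg)
  st <- popgenscan:::window_stats_from_sims(sims)
  expect_true(all(st$fst_X_Y[1:15] > 0.9))
  expect_gt(mean(st$dxy_X_Y[1:15]), median(st$dxy_X_Y[16:30]))
})

test_that("signal specs validate frequencies against the samples", {
  model <- default_demography(10)
  cfg <- simulation_config(n_windows = 2, seed = 1)
  sims <- simulate_windows(model, cfg)
  expect_error(inject_signal(sims, signal_spec("balanced", 1,
                                               freq_A = 1.5)), "0, 1")
  expect_error(inject_signal(sims, signal_spec("balanced", 1,
                                               freq_A = 0.001)),
               "incompatible|intermediate")
  expect_error(inject_signal(sims, signal_spec("sorted", 1, freq_A = 0.5)),
               "near-fixed")
  expect_error(inject_signal(sims, signal_spec("sorted", 1, freq_A = 1)),
               "both haplogroups")
  # empty target list: identity
  s2 <- inject_signal(sims, signal_spec("balanced", integer(0)))
  expect_identical(s2$windows, sims$windows)
})

test_that("the injected-signal window pi rises with haplogroup TMRCA", {
  model <- single_pop_model(ne = 10000, n_diploid = 10)
  mean_pi_at <- function(tmrca, seed) {
    cfg <- simulation_config(n_windows = 50, recombination_cM_per_Mb = 0,
                             seed = seed,
                             signal_specs = list(
                               signal_spec("balanced", 1:50,
                                           tmrca_generations = tmrca)))
    mean(vapply(simulate_windows(model, cfg)$windows,
                function(w) window_pi(w$hap, 20000), numeric(1)))
  }
  p1 <- mean_pi_at(2e5, 61); p2 <- mean_pi_at(6e5, 62); p3 <- mean_pi_at(2e6, 63)
  expect_lt(p1, p2); expect_lt(p2, p3)
})

test_that("outgroup divergence follows the branch-length expectation", {
  model <- single_pop_model(ne = 5000, n_diploid = 5)
  D <- 1e6
  cfg <- simulation_config(n_windows = 200, recombination_cM_per_Mb = 0,
                           seed = 71,
                           outgroup_divergence_generations = D)
  sims <- add_outgroup(simulate_windows(model, cfg))
  # expected pairwise differences between outgroup and one ingroup
  # sequence: 2 D mu L
  mu <- mu_per_generation(model); L <- 20000
  diffs <- vapply(sims$windows, function(w)
    sum(w$hap[1, ] != w$outgroup), numeric(1))
  expected <- 2 * D * mu * L
  expect_lt(abs(mean(diffs) - expected), 3 * sd(diffs) / sqrt(length(diffs)))
  # polarization: outgroup carries the ancestral allele at every
  # ingroup-segregating site, so folded = fold(unfolded)
  w <- sims$windows[[1]]
  seg <- colSums(w$hap) > 0 & colSums(w$hap) < nrow(w$hap)
  expect_true(all(w$outgroup[seg] == 0L))
  pops <- sims$sample_pops
  su <- downsampled_sfs(w$hap, pops, targets = c(A = 10), fold = FALSE)
  sf <- downsampled_sfs(w$hap, pops, targets = c(A = 10), fold = TRUE)
  expect_equal(sf$spectra$A, fold_sfs(su$spectra$A))
  # divergence must exceed the ingroup TMRCA
  expect_error(add_outgroup(simulate_windows(model, cfg), 1),
               "exceeding")
})

test_that("inbreeding collapse controls heterozygosity", {
  model <- single_pop_model(ne = 10000, n_diploid = 20)
  cfg <- simulation_config(n_windows = 30, recombination_cM_per_Mb = 0,
                           seed = 81)
  sims <- simulate_windows(model, cfg)
  gs1 <- collapse_to_inbred(sims, selfing_fraction = 1)
  expect_true(all(vapply(gs1$windows, function(w)
    sum(w$geno == 1L), numeric(1)) == 0))
  set.seed(5)
  gs0 <- collapse_to_inbred(sims, selfing_fraction = 0)
  # Hardy-Weinberg: E[het at a site] = 2 p q with p from the two drawn
  # haplotypes; compare the realized het count against the expectation
  # computed from the paired haplotypes
  hets <- 0; exp_hets <- 0
  for (w in gs0$windows) {
    hets <- hets + sum(w$geno == 1L)
    exp_hets <- exp_hets + sum(w$allele1 != w$allele2)
  }
  expect_equal(hets, exp_hets)   # non-selfed keeps both haplotypes
  set.seed(7); a <- collapse_to_inbred(sims, 0.5)
  set.seed(7); b <- collapse_to_inbred(sims, 0.5)
  expect_identical(a$windows, b$windows)
})

test_that("selfing draws match the configured fraction", {
  model <- single_pop_model(ne = 1000, n_diploid = 50)
  cfg <- simulation_config(n_windows = 40, recombination_cM_per_Mb = 0,
                           seed = 83)
  sims <- simulate_windows(model, cfg)
  set.seed(11)
  gs <- collapse_to_inbred(sims, selfing_fraction = 0.7)
  frac <- mean(vapply(gs$windows, function(w) mean(w$selfed), numeric(1)))
  se <- sqrt(0.7 * 0.3 / (50 * 40))
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("geography assignment is anchored and metric", {
  samples <- data.frame(sample = paste0("s", 1:6),
                        group = rep(c("A", "B"), each = 3))
  anchors <- data.frame(group = c("A", "B"), lat = c(45, 45),
                        lon = c(-114, -114))
  geo <- assign_geography(samples, anchors, spacing_km = 0)
  d <- geographic_distance_matrix(geo$lat, geo$lon)
  expect_true(all(d == 0))
  # two anchors ~100 km apart (great-circle check)
  anchors2 <- data.frame(group = c("A", "B"), lat = c(45, 45 + 100 / 111.195),
                         lon = c(-114, -114))
  geo2 <- assign_geography(samples, anchors2, spacing_km = 0)
  d2 <- geographic_distance_matrix(geo2$lat, geo2$lon)
  expect_lt(abs(d2[1, 4] - 100), 0.5)
  expect_error(assign_geography(samples,
                                data.frame(group = "A", lat = 0, lon = 0)),
               "anchor")
})

test_that("rendered VCF honors the depth model and keeps truth intact", {
  model <- single_pop_model(ne = 20000, n_diploid = 8)
  base_cfg <- function(dm) simulation_config(
    n_windows = 4, recombination_cM_per_Mb = 0, seed = 91, depth_model = dm)
  # mean depth 0: everything missing, callable counts 0
  sims <- simulate_windows(model, base_cfg(list(mean_depth = 0,
                                                base_error_rate = 0,
                                                het_balance = 0.5)))
  gs <- collapse_to_inbred(sims, 0.9)
  out <- render_vcf(gs, tempfile("vcf0"))
  gm <- read_genotype_matrix(out$paths$vcf)
  expect_true(all(is.na(gm$gt)))
  calls <- read.table(out$paths$callable, header = TRUE, sep = "\t")
  expect_true(all(calls$n_callable == 0))
  # error 0, depth 100: perfect concordance with truth
  sims2 <- simulate_windows(model, base_cfg(list(mean_depth = 100,
                                                 base_error_rate = 0,
                                                 het_balance = 0.5)))
  gs2 <- collapse_to_inbred(sims2, 0.9)
  out2 <- render_vcf(gs2, tempfile("vcf100"))
  gm2 <- read_genotype_matrix(out2$paths$vcf)
  truth2 <- do.call(cbind, lapply(gs2$windows, function(w) w$geno))
  r <- concordance(gm2$gt, truth2)
  expect_equal(r$TPR, 1); expect_equal(r$MR, 0)
  # every VCF site maps to exactly one truth site; samples conserved
  expect_equal(ncol(gm2$gt), ncol(truth2))
  expect_equal(gm2$samples, gs2$samples)
  # depth 5, error 1%: false heterozygotes appear, and the het depth
  # filter (< 20 reads) masks them
  sims3 <- simulate_windows(model, base_cfg(list(mean_depth = 5,
                                                 base_error_rate = 0.01,
                                                 het_balance = 0.5)))
  gs3 <- collapse_to_inbred(sims3, 1)     # truth has zero hets
  out3 <- render_vcf(gs3, tempfile("vcf5"))
  gm3 <- read_genotype_matrix(out3$paths$vcf)
  expect_gt(sum(gm3$gt == 1L, na.rm = TRUE), 0)
  masked <- mask_genotypes(gm3)
  expect_equal(sum(masked$gt == 1L & gm3$dp < 20, na.rm = TRUE), 0)
})

test_that("rendered files are byte-identical under a fixed seed", {
  model <- default_demography(3)
  cfg <- simulation_config(n_windows = 3, seed = 17,
                           signal_specs = list(signal_spec("sorted", 2)))
  render_once <- function(dir) {
    sims <- simulate_windows(model, cfg)
    gs <- collapse_to_inbred(sims)
    render_vcf(gs, dir)
  }
  d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
  render_once(d1); render_once(d2)
  for (f in c("sim.vcf", "callable.tsv", "truth_regions.bed",
              "truth_genotypes.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
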