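#' Simulation configuration
#'
#' Bundles the window-level settings of the synthetic-data generator.
#'
#' @param n_windows number of independent 20-kb windows to simulate.
#' @param window_length_bp window length in bp (default 20,000).
#' @param recombination_cM_per_Mb within-window recombination rate; handled
#'   by a block-independence approximation (see [n_recombination_blocks()]).
#' @param seed integer seed; a fixed seed makes all emitted files
#'   byte-identical across runs. `NULL` uses the current RNG state.
#' @param outgroup_divergence_generations time of the outgroup split,
#'   generations before present (default 2.5e6); must exceed every ingroup
#'   TMRCA.
#' @param signal_specs list of [signal_spec()] objects.
#' @param depth_model list with `mean_depth` (Poisson mean per genotype),
#'   `base_error_rate` (per-read probability of reading the other allele)
#'   and `het_balance` (reference-read probability for a true heterozygote,
#'   default 0.5 so allelic depths are Binomial(depth, 0.5)).
#' @param n_chromosomes chromosomes the windows are tiled onto when
#'   rendering coordinates (default 7).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_windows,
                              window_length_bp = 20000L,
                              recombination_cM_per_Mb = 1,
                              seed = NULL,
                              outgroup_divergence_generations = 2.5e6,
                              signal_specs = list(),
                              depth_model = list(mean_depth = 5,
                                                 base_error_rate = 0.01,
                                                 het_balance = 0.5),
                              n_chromosomes = 7L) {
  stopifnot(n_windows >= 1, window_length_bp > 0,
            recombination_cM_per_Mb >= 0,
            outgroup_divergence_generations > 0)
  structure(list(n_windows = as.integer(n_windows),
                 window_length_bp = as.integer(window_length_bp),
                 recombination_cM_per_Mb = recombination_cM_per_Mb,
                 seed = seed,
                 outgroup_divergence_generations = outgroup_divergence_generations,
                 signal_specs = signal_specs,
                 depth_model = depth_model,
                 n_chromosomes = as.integer(n_chromosomes)),
            class = "simulation_config")
}

#' Number of non-recombining blocks used to approximate recombination
#'
#' Within-window recombination is approximated by cutting the window into
#' `k = max(1, round(4 * r * Ne))` independent blocks, where `r` is the
#' window's genetic length in Morgans and `Ne` a reference diploid size
#' (the most ancestral size of the model's root population). `k` is capped
#' at 64: beyond that the inter-window variance reduction the approximation
#' exists to produce has saturated.
#'
#' @param config a `simulation_config`.
#' @param model a `demographic_model`.
#' @return integer block count.
#' @export
n_recombination_blocks <- function(config, model) {
  morgans <- config$recombination_cM_per_Mb *
    (config$window_length_bp / 1e6) / 100
  root <- root_population(model)
  ep <- model$epochs[[root]]
  ne_ref <- ep$ne[nrow(ep)]
  min(64L, max(1L, as.integer(round(4 * morgans * ne_ref))))
}

root_population <- function(model) {
  pn <- as.character(model$populations$name)
  if (nrow(model$splits)) pn[!pn %in% model$splits$derived] else pn[1]
}

#' Simulate independent coalescent windows
#'
#' Each window is an independent realization of the structured coalescent
#' under `model`, with mutations placed under the infinite-sites model at
#' rate `mu_per_site_per_year * generation_time_years` per site per
#' generation. Haplotype count per population is twice the sampled diploid
#' count (inbreeding collapse happens later, in [collapse_to_inbred()]).
#'
#' @param model a `demographic_model` (validated before use).
#' @param config a `simulation_config`.
#' @return object of class `window_sims`: a list with `windows` (per window:
#'   `pos`, 1-based positions within the window; `hap`, haplotypes x sites
#'   0/1 matrix; `block`, per-site block index; `tmrca`, per-block TMRCA in
#'   generations), `sample_pops` (population factor per haplotype row),
#'   `model` and `config`.
#' @export
simulate_windows <- function(model, config) {
  validate_demographic_model(model)
  if (!is.null(config$seed)) set.seed(config$seed)
  args <- model_to_cpp_args(model)
  k <- n_recombination_blocks(config, model)
  wins <- .sim_windows_cpp(args$sample_sizes, args$epoch_deme,
                           args$epoch_start, args$epoch_ne,
                           args$split_time, args$split_derived,
                           args$split_ancestral, args$mig,
                           mu_per_generation(model),
                           config$window_length_bp, k, config$n_windows)
  pn <- as.character(model$populations$name)
  pops <- factor(rep(pn, times = 2L * model$populations$n_diploid),
                 levels = pn)
  sims <- structure(list(windows = wins, sample_pops = pops,
                         model = model, config = config,
                         signal_windows = integer(0)),
                    class = "window_sims")
  if (length(config$signal_specs)) {
    for (spec in config$signal_specs) sims <- inject_signal(sims, spec)
  }
  sims
}

#' Specify a balanced or sorted haplogroup signal
#'
#' A signal region carries two deep ancestral haplogroups (A and B) whose
#' most recent common ancestor predates the background genealogy.
#' `balanced` keeps both haplogroups at intermediate frequency in every
#' population (elevating within-population diversity but not
#' differentiation); `sorted` fixes alternative haplogroups in different
#' populations (elevating FST and dXY).
#'
#' @param kind `"balanced"` or `"sorted"`.
#' @param windows integer indices of the target windows.
#' @param tmrca_generations coalescence time of the two haplogroups,
#'   generations before present (default 5e5, i.e. ~1 million years at a
#'   2-year generation time).
#' @param freq_A frequency of haplogroup A per population: a single number
#'   or a vector named by population. Balanced signals require
#'   intermediate frequencies (default 0.5 everywhere); sorted signals
#'   require every population near fixation for one haplogroup
#'   (freq_A >= 0.9 or <= 0.1) with both haplogroups fixed somewhere.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(kind = c("balanced", "sorted"), windows,
                        tmrca_generations = 5e5, freq_A = NULL) {
  kind <- match.arg(kind)
  if (is.null(freq_A)) freq_A <- if (kind == "balanced") 0.5 else NA_real_
  stopifnot(tmrca_generations > 0)
  structure(list(kind = kind, windows = as.integer(windows),
                 tmrca_generations = tmrca_generations, freq_A = freq_A),
            class = "signal_spec")
}

signal_freqs <- function(spec, pop_names) {
  f <- spec$freq_A
  if (length(f) == 1L && is.null(names(f))) {
    if (spec$kind == "sorted" && is.na(f)) {
      # default sorted layout: haplogroup A fixed in the first half of the
      # populations, B in the rest
      f <- setNames(rep(c(1, 0), c(ceiling(length(pop_names) / 2),
                                   floor(length(pop_names) / 2))), pop_names)
    } else {
      f <- setNames(rep(f, length(pop_names)), pop_names)
    }
  }
  if (!all(pop_names %in% names(f)))
    stop("freq_A must cover every population")
  f <- f[pop_names]
  if (any(f < 0 | f > 1)) stop("haplogroup frequencies must be in [0, 1]")
  if (spec$kind == "balanced" && any(f <= 0 | f >= 1))
    stop("balanced signals need intermediate haplogroup frequencies in every population")
  if (spec$kind == "sorted") {
    if (any(f > 0.1 & f < 0.9))
      stop("sorted signals need near-fixed haplogroups (freq_A <= 0.1 or >= 0.9) in every population")
    if (all(f >= 0.9) || all(f <= 0.1))
      stop("sorted signals need both haplogroups fixed in at least one population")
  }
  f
}

#' Inject a haplogroup signal into simulated windows
#'
#' Replaces each target window by a grafted genealogy: the sampled
#' haplotypes are partitioned into haplogroups A and B according to the
#' spec's per-population frequencies, each haplogroup coalesces under the
#' demographic model on its own, and the two sub-genealogies are joined at
#' the spec's TMRCA. Mutations on the two deep stem branches become sites
#' fixed between haplogroups. Signal windows are simulated as single
#' non-recombining blocks.
#'
#' @param sims a `window_sims` object.
#' @param spec a [signal_spec()].
#' @return the modified `window_sims`, with `signal_windows` updated.
#' @export
inject_signal <- function(sims, spec) {
  stopifnot(inherits(sims, "window_sims"), inherits(spec, "signal_spec"))
  if (!length(spec$windows)) return(sims)
  if (any(spec$windows < 1 | spec$windows > length(sims$windows)))
    stop("signal spec targets windows outside the simulated range")
  model <- sims$model
  pn <- as.character(model$populations$name)
  n_hap <- 2L * model$populations$n_diploid
  f <- signal_freqs(spec, pn)
  nA <- as.integer(round(f * n_hap))
  if (any(f > 0 & nA == 0) || any(f < 1 & nA == n_hap))
    stop("haplogroup frequency incompatible with sampled haplotype counts")
  mu <- mu_per_generation(model)
  L <- sims$config$window_length_bp
  Tg <- spec$tmrca_generations
  pop_idx <- split(seq_along(sims$sample_pops), sims$sample_pops)

  # within-haplogroup genealogies are conditioned on coalescing before the
  # graft time (the grafted model implies no within-class lineage survives
  # past the haplogroup split), via rejection sampling
  sim_class <- function(nn) {
    args <- model_to_cpp_args(model, sample_haploids = nn)
    for (try in 1:1000) {
      s <- .sim_windows_cpp(args$sample_sizes, args$epoch_deme,
                            args$epoch_start, args$epoch_ne,
                            args$split_time, args$split_derived,
                            args$split_ancestral, args$mig, mu, L, 1L, 1L)[[1]]
      if (max(s$tmrca, 0) < Tg) return(s)
    }
    stop("signal TMRCA does not predate the within-haplogroup genealogies; increase tmrca_generations")
  }

  for (w in spec$windows) {
    # haplogroup membership: random draw of nA haplotypes per population
    memb_A <- unlist(lapply(seq_along(pn), function(p) {
      idx <- pop_idx[[pn[p]]]
      if (nA[p] == 0) integer(0) else sort(sample(idx, nA[p]))
    }))
    memb_B <- setdiff(seq_along(sims$sample_pops), memb_A)
    simA <- sim_class(nA)
    simB <- sim_class(n_hap - nA)
    tA <- max(simA$tmrca, 0)
    tB <- max(simB$tmrca, 0)
    n_all <- length(sims$sample_pops)
    build <- function(sub, members) {
      if (!length(members) || !ncol(sub$hap)) {
        return(matrix(0L, n_all, 0L))
      }
      m <- matrix(0L, n_all, ncol(sub$hap))
      m[members, ] <- sub$hap
      m
    }
    hapA <- build(simA, memb_A)
    hapB <- build(simB, memb_B)
    # stem mutations: fixed within one haplogroup, absent from the other
    n_stem_A <- rpois(1, mu * L * max(Tg - tA, 0))
    n_stem_B <- rpois(1, mu * L * max(Tg - tB, 0))
    stemA <- matrix(0L, n_all, n_stem_A); stemA[memb_A, ] <- 1L
    stemB <- matrix(0L, n_all, n_stem_B); stemB[memb_B, ] <- 1L
    hap <- cbind(hapA, hapB, stemA, stemB)
    S <- ncol(hap)
    pos <- sort(sample.int(L, S))
    sims$windows[[w]] <- list(pos = pos, hap = hap,
                              block = rep(1L, S), tmrca = Tg)
    sims$signal_windows <- sort(union(sims$signal_windows, w))
    attr(sims$windows[[w]], "signal_kind") <- spec$kind
  }
  if (is.null(sims$signal_kinds)) sims$signal_kinds <- character(0)
  sims$signal_kinds[as.character(spec$windows)] <- spec$kind
  sims
}

#' Add an outgroup sequence to simulated windows
#'
#' Joins a single outgroup lineage to each window's genealogy at
#' `divergence_generations`. Under infinite sites the outgroup carries the
#' ancestral allele at every ingroup segregating site; in addition,
#' mutations on the outgroup branch (outgroup-specific) and on the ingroup
#' stem (fixed derived in the whole ingroup) are appended as extra,
#' ingroup-monomorphic sites so that divergence to the outgroup is defined
#' per window.
#'
#' @param sims a `window_sims`.
#' @param divergence_generations outgroup split time, generations; defaults
#'   to the config's `outgroup_divergence_generations`. Must exceed every
#'   ingroup TMRCA.
#' @return `window_sims` with per-window `outgroup` (allele of the outgroup
#'   at each site, including appended divergent sites).
#' @export
add_outgroup <- function(sims, divergence_generations = NULL) {
  stopifnot(inherits(sims, "window_sims"))
  D <- divergence_generations %||% sims$config$outgroup_divergence_generations
  mu <- mu_per_generation(sims$model)
  L <- sims$config$window_length_bp
  n_hap <- length(sims$sample_pops)
  for (w in seq_along(sims$windows)) {
    win <- sims$windows[[w]]
    tm <- win$tmrca
    if (any(tm > D))
      stop(sprintf("window %d has TMRCA %g exceeding outgroup divergence %g",
                   w, max(tm), D))
    nb <- length(tm)
    og <- rep(0L, length(win$pos))
    extra_pos <- integer(0); extra_og <- integer(0); extra_blk <- integer(0)
    extra_fixed <- integer(0)
    for (b in seq_len(nb)) {
      lo <- floor((b - 1) * L / nb); hi <- floor(b * L / nb)
      Lb <- hi - lo
      # branch lengths: outgroup branch D, ingroup stem D - tmrca
      n_og <- rpois(1, mu * Lb * D)
      n_stem <- rpois(1, mu * Lb * (D - tm[b]))
      npick <- n_og + n_stem
      if (npick == 0) next
      avail <- setdiff(seq.int(lo + 1L, hi), win$pos[win$block == b])
      npick <- min(npick, length(avail))
      n_og <- min(n_og, npick)
      p <- sample(avail, npick)
      extra_pos <- c(extra_pos, p)
      extra_og <- c(extra_og, rep(c(1L, 0L), c(n_og, npick - n_og)))
      extra_fixed <- c(extra_fixed, rep(c(0L, 1L), c(n_og, npick - n_og)))
      extra_blk <- c(extra_blk, rep(b, npick))
    }
    if (length(extra_pos)) {
      extra_hap <- matrix(rep(extra_fixed, each = n_hap), n_hap,
                          length(extra_pos))
      pos <- c(win$pos, extra_pos)
      ord <- order(pos)
      kind <- attr(win, "signal_kind")
      win <- list(pos = pos[ord],
                  hap = cbind(win$hap, extra_hap)[, ord, drop = FALSE],
                  block = c(win$block, extra_blk)[ord],
                  tmrca = win$tmrca,
                  outgroup = c(og, extra_og)[ord])
      if (!is.null(kind)) attr(win, "signal_kind") <- kind
    } else {
      win$outgroup <- og
    }
    sims$windows[[w]] <- win
  }
  sims$outgroup_divergence <- D
  sims
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse haplotypes into inbred diploid genotypes
#'
#' Emulates a highly selfing species: each diploid individual is formed
#' from two consecutive haplotypes of its population; with probability
#' `selfing_fraction` the individual is made fully homozygous by
#' duplicating the first haplotype of the pair, otherwise it keeps the two
#' distinct haplotypes.
#'
#' @param sims a `window_sims` (after any signal injection / outgroup).
#' @param selfing_fraction probability an individual is fully homozygous
#'   (default 0.98).
#' @return object of class `genotype_sims`: per window a dosage matrix
#'   (individuals x sites, values 0/1/2), plus `sample_pops`, sample ids,
#'   and the per-individual selfing draw (truth).
#' @export
collapse_to_inbred <- function(sims, selfing_fraction = 0.98) {
  stopifnot(inherits(sims, "window_sims"),
            selfing_fraction >= 0, selfing_fraction <= 1)
  n_dip <- sims$model$populations$n_diploid
  if (any(table(sims$sample_pops) %% 2L != 0L))
    stop("haplotype count per population must be even")
  pn <- as.character(sims$model$populations$name)
  pops <- factor(rep(pn, times = n_dip), levels = pn)
  hap1 <- seq(1, 2 * sum(n_dip), by = 2)
  hap2 <- hap1 + 1L
  windows <- vector("list", length(sims$windows))
  # one selfing draw per individual per window
  for (w in seq_along(sims$windows)) {
    win <- sims$windows[[w]]
    selfed <- runif(length(hap1)) < selfing_fraction
    a1 <- win$hap[hap1, , drop = FALSE]
    a2 <- win$hap[hap2, , drop = FALSE]
    a2[selfed, ] <- a1[selfed, , drop = FALSE]
    g <- a1 + a2
    windows[[w]] <- list(pos = win$pos, geno = g, allele1 = a1, allele2 = a2,
                         selfed = selfed, outgroup = win$outgroup,
                         tmrca = win$tmrca)
    attr(windows[[w]], "signal_kind") <- attr(win, "signal_kind")
  }
  structure(list(windows = windows, sample_pops = pops,
                 samples = paste0(rep(pn, times = n_dip), "_",
                                  unlist(lapply(n_dip, seq_len))),
                 model = sims$model, config = sims$config,
                 signal_windows = sims$signal_windows,
                 signal_kinds = sims$signal_kinds,
                 outgroup_divergence = sims$outgroup_divergence),
            class = "genotype_sims")
}

#' Assign geographic coordinates to samples
#'
#' Places each population at an anchor point and spreads its samples along
#' a 1-D (eastward) gradient with optional Gaussian jitter, so that
#' stepping-stone simulations with local migration show isolation by
#' distance. Deterministic under a fixed seed.
#'
#' @param samples data.frame with columns `sample` and `group`.
#' @param anchors data.frame with columns `group`, `lat`, `lon`.
#' @param spacing_km eastward spacing between consecutive samples of a
#'   population (default 1 km).
#' @param jitter_km standard deviation of isotropic jitter (default 0).
#' @return data.frame (sample, group, lat, lon).
#' @export
assign_geography <- function(samples, anchors, spacing_km = 1,
                             jitter_km = 0) {
  stopifnot(all(c("sample", "group") %in% names(samples)),
            all(c("group", "lat", "lon") %in% names(anchors)))
  if (!all(samples$group %in% anchors$group))
    stop("every group needs an anchor")
  km_per_deg_lat <- 111.195  # mean-radius great-circle km per degree
  out <- samples
  out$lat <- NA_real_; out$lon <- NA_real_
  for (g in unique(samples$group)) {
    idx <- which(samples$group == g)
    a <- anchors[match(g, anchors$group), ]
    off <- (seq_along(idx) - (length(idx) + 1) / 2) * spacing_km
    jx <- if (jitter_km > 0) rnorm(length(idx), 0, jitter_km) else 0
    jy <- if (jitter_km > 0) rnorm(length(idx), 0, jitter_km) else 0
    out$lat[idx] <- a$lat + jy / km_per_deg_lat
    out$lon[idx] <- a$lon + (off + jx) /
      (km_per_deg_lat * cos(a$lat * pi / 180))
  }
  out
}
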