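#' Simulate a genome and compute the windowed scan statistics
#'
#' End-to-end synthetic-genome experiment: simulates coalescent windows
#' under the model (with any signal regions in the config), collapses
#' haplotypes to inbred diploids, haploidizes one allele per individual
#' (the treatment applied to real inbred genotypes), and computes
#' per-window statistics: pi, S and Tajima's D per group; Weir-Cockerham
#' FST (with numerator/denominator sums) and dXY per group pair; optionally
#' Fay & Wu's H and divergence to a simulated outgroup. Windows are
#' processed in chunks so genome-scale runs stay within memory.
#'
#' @param model a `demographic_model`.
#' @param config a `simulation_config` (its `seed` drives everything).
#' @param selfing_fraction passed to [collapse_to_inbred()].
#' @param outgroup logical; add an outgroup and outgroup statistics.
#' @param chunk_size windows simulated per chunk (default 250).
#' @param stats_set `"full"` (group and pair statistics) or `"pi"` (group
#'   diversity only, e.g. for neutral replicate genomes feeding the
#'   shared-island false-positive experiment).
#' @return list with `stats` (data.frame, one row per window: chrom,
#'   start, end, n_callable, per-group and per-pair columns), `truth`
#'   (data.frame of injected signal regions) and `layout`.
#' @export
scan_experiment <- function(model, config, selfing_fraction = 0.98,
                            outgroup = FALSE, chunk_size = 250L,
                            stats_set = c("full", "pi")) {
  validate_demographic_model(model)
  stats_set <- match.arg(stats_set)
  if (!is.null(config$seed)) set.seed(config$seed)
  lay <- window_layout(config)
  n <- config$n_windows
  pn <- as.character(model$populations$name)
  pairs <- if (length(pn) > 1 && stats_set == "full") combn(pn, 2) else NULL
  specs <- config$signal_specs
  rows <- vector("list", ceiling(n / chunk_size))
  ci <- 0L
  for (a in seq(1L, n, by = chunk_size)) {
    b <- min(a + chunk_size - 1L, n)
    sub <- lapply(specs, function(sp) {
      w <- sp$windows[sp$windows >= a & sp$windows <= b]
      if (!length(w)) return(NULL)
      s <- sp; s$windows <- w - a + 1L; s
    })
    sub <- Filter(Negate(is.null), sub)
    cfg <- config
    cfg$n_windows <- b - a + 1L
    cfg$seed <- NULL
    cfg$signal_specs <- sub
    sims <- simulate_windows(model, cfg)
    if (outgroup) sims <- add_outgroup(sims)
    gsims <- collapse_to_inbred(sims, selfing_fraction)
    st <- chunk_window_stats(gsims, pn, pairs, outgroup)
    st <- cbind(lay[a:b, c("chrom", "start", "end")], st)
    ci <- ci + 1L
    rows[[ci]] <- st
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  stats <- cbind(window = seq_len(n), stats)
  truth <- signal_truth_regions(config, lay)
  list(stats = stats, truth = truth, layout = lay)
}

chunk_window_stats <- function(gsims, pn, pairs, outgroup) {
  L <- gsims$config$window_length_bp
  pops <- gsims$sample_pops
  n_per <- table(pops)[pn]
  out <- lapply(gsims$windows, function(win) {
    hap <- haploidize(win$geno)
    # haploidized simulated data has no missing calls, so group statistics
    # reduce to closed forms in the per-group derived counts
    cnt <- if (ncol(hap)) rowsum(hap, pops)[pn, , drop = FALSE]
           else matrix(0L, length(pn), 0L)
    row <- list(n_callable = L, n_snps = ncol(hap))
    for (p in pn) {
      i <- cnt[p, ]; np <- n_per[[p]]
      pi_tot <- sum(2 * i * (np - i) / (np * (np - 1)))
      row[[paste0("pi_", p)]] <- pi_tot / L
      seg <- i > 0 & i < np
      S <- sum(seg)
      row[[paste0("S_", p)]] <- S
      if (S > 0) {
        k <- tajima_constants(np)
        theta_tot <- S / k$a1
        row[[paste0("theta_", p)]] <- theta_tot / L
        row[[paste0("tajd_", p)]] <-
          (pi_tot - theta_tot) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
      } else {
        row[[paste0("theta_", p)]] <- 0
        row[[paste0("tajd_", p)]] <- NA_real_
      }
      if (outgroup && !is.null(win$outgroup))
        row[[paste0("fwh_", p)]] <-
          window_fay_wu_h(hap[pops == p, , drop = FALSE], win$outgroup)
    }
    if (!is.null(pairs)) for (j in seq_len(ncol(pairs))) {
      pr <- pairs[, j]
      tag <- paste0(pr[1], "_", pr[2])
      i1 <- cnt[pr[1], ]; n1 <- n_per[[pr[1]]]
      i2 <- cnt[pr[2], ]; n2 <- n_per[[pr[2]]]
      f <- fst_from_counts(i1, n1, i2, n2)
      row[[paste0("fst_", tag)]] <- f$fst
      p1 <- i1 / n1; p2 <- i2 / n2
      dxy <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
      row[[paste0("dxy_", tag)]] <- dxy
      row[[paste0("da_", tag)]] <-
        da_window(dxy, row[[paste0("pi_", pr[1])]],
                  row[[paste0("pi_", pr[2])]])
      if (outgroup && !is.null(win$outgroup)) {
        d1 <- dxy_to_outgroup(hap, win$outgroup, pops, pr[1], L)
        d2 <- dxy_to_outgroup(hap, win$outgroup, pops, pr[2], L)
        row[[paste0("rnd_", tag)]] <- rnd_window(dxy, d1, d2)
      }
    }
    as.data.frame(row)
  })
  do.call(rbind, out)
}

# Weir-Cockerham ratio-of-averages FST from complete haploid counts
# (haploids treated as homozygous diploids: hbar = 0)
fst_from_counts <- function(i1, n1, i2, n2) {
  p1 <- i1 / n1; p2 <- i2 / n2
  poly <- !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(poly)) return(list(fst = NA_real_, num = 0, den = 0))
  p1 <- p1[poly]; p2 <- p2[poly]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  num <- sum(a); den <- sum(a + b)
  list(fst = if (den > 0) num / den else NA_real_, num = num, den = den)
}

signal_truth_regions <- function(config, lay) {
  specs <- config$signal_specs
  if (!length(specs)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), kind = character(0)))
  }
  out <- lapply(specs, function(sp) {
    d <- lay[sp$windows, c("chrom", "start", "end")]
    d$kind <- sp$kind
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan for shared high-diversity regions
#'
#' Z-transforms per-group window diversity, calls pi-islands at
#' `Z >= threshold` in each group, intersects them across all groups and
#' merges shared islands separated by less than `max_gap` into candidate
#' balancing-selection regions.
#'
#' @param stats data.frame from [scan_experiment()] (or equivalent) with
#'   `chrom`, `start`, `end` and `pi_<group>` columns.
#' @param groups group names (default: parsed from the `pi_` columns).
#' @param threshold Z threshold (default 2, inclusive).
#' @param max_gap merge gap in bp (default 1.5e6, strict `<`).
#' @return list with `islands` (per-group `region_set`), `shared` (window
#'   ids), `regions` (merged `region_set`) and `z` (matrix of Z scores).
#' @export
scan_pi_islands <- function(stats, groups = NULL, threshold = 2,
                            max_gap = 1500000) {
  if (is.null(groups))
    groups <- sub("^pi_", "", grep("^pi_", names(stats), value = TRUE))
  z <- sapply(groups, function(g) z_transform(stats[[paste0("pi_", g)]]))
  islands <- lapply(groups, function(g)
    call_islands(stats, z[, g], threshold = threshold))
  names(islands) <- groups
  shared <- shared_islands(islands)
  regions <- merge_regions(stats[shared, c("chrom", "start", "end")],
                           max_gap = max_gap)
  list(islands = islands, shared = shared, regions = regions, z = z)
}

#' Scan for divergence islands
#'
#' Removes windows overlapping `mask` (e.g. detected balancing-selection
#' regions), Z-transforms per-pair FST and calls FST-islands at
#' `Z >= threshold`.
#'
#' @param stats data.frame with `chrom`, `start`, `end` and `fst_<pair>`
#'   columns.
#' @param mask `region_set` or data.frame of regions excluded before the
#'   Z-transform (default none).
#' @param pairs pair tags (default: parsed from the `fst_` columns,
#'   skipping the `fst_*_num`/`_den` component sums).
#' @param threshold Z threshold (default 2).
#' @return list with `stats` (masked table), `islands` (per-pair
#'   `region_set`) and `z`.
#' @export
scan_fst_islands <- function(stats, mask = NULL, pairs = NULL,
                             threshold = 2) {
  if (!is.null(mask)) stats <- exclude_regions(stats, mask)
  if (is.null(pairs)) {
    pairs <- grep("^fst_", names(stats), value = TRUE)
    pairs <- sub("^fst_", "", pairs[!grepl("_(num|den)$", pairs)])
  }
  z <- sapply(pairs, function(p) z_transform(stats[[paste0("fst_", p)]]))
  islands <- lapply(pairs, function(p)
    call_islands(stats, z[, p], threshold = threshold))
  names(islands) <- pairs
  list(stats = stats, islands = islands, z = z)
}

#' Fraction of truth regions covered by detected regions
#'
#' @param truth,detected data.frames (chrom, start, end).
#' @return fraction of the total truth span overlapped by detection.
#' @export
region_overlap_fraction <- function(truth, detected) {
  if (!nrow(truth)) return(NA_real_)
  if (!nrow(detected)) return(0)
  tg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1L, truth$end)))
  dg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    detected$chrom, IRanges::IRanges(detected$start + 1L, detected$end)))
  ov <- GenomicRanges::intersect(tg, dg)
  sum(IRanges::width(ov)) / sum(IRanges::width(tg))
}

#' Write a region set to BED
#'
#' 0-based half-open BED with the region kind as name.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- regions$runs
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = regions$kind)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
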