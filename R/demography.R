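#' Construct a demographic model
#'
#' A demographic model describes a set of populations, their epoch-wise
#' diploid effective sizes looking backward in time, population splits
#' (mergers backward in time), a per-generation migration matrix, and the
#' mutation-rate clock used to convert between time units.
#'
#' @param populations data.frame with columns `name` and `n_diploid`
#'   (sampled diploid individuals per population).
#' @param epochs named list (one entry per population) of data.frames with
#'   columns `start_gen` (start of the epoch, generations before present;
#'   the first epoch of every population must start at 0), `ne` (diploid
#'   effective size) and optionally `growth` (`"constant"` or
#'   `"exponential"`; exponential epochs interpolate log-linearly to the
#'   next, older epoch and are discretized internally).
#' @param splits data.frame with columns `time_gen`, `derived`, `ancestral`:
#'   at `time_gen` generations before present, lineages of the `derived`
#'   population merge into `ancestral`.
#' @param migration square matrix of per-generation migration rates
#'   m\[i, j\] (backward probability that a lineage in i derives from j), or
#'   a single number applied to all off-diagonal entries.
#' @param mu_per_site_per_year substitution rate per site per year.
#' @param generation_time_years generation time in years.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(populations, epochs, splits = NULL,
                              migration = 0,
                              mu_per_site_per_year = 7e-9,
                              generation_time_years = 2) {
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "n_diploid") %in% names(populations)))
  pn <- as.character(populations$name)
  P <- length(pn)
  if (anyDuplicated(pn)) stop("duplicated population names")
  if (is.null(splits)) {
    splits <- data.frame(time_gen = numeric(0), derived = character(0),
                         ancestral = character(0))
  }
  if (length(migration) == 1L) {
    m <- matrix(migration, P, P, dimnames = list(pn, pn))
    diag(m) <- 0
    migration <- m
  }
  model <- structure(
    list(populations = populations,
         epochs = epochs,
         splits = as.data.frame(splits),
         migration = migration,
         mu_per_site_per_year = mu_per_site_per_year,
         generation_time_years = generation_time_years),
    class = "demographic_model")
  validate_demographic_model(model)
  model
}

#' Validate a demographic model
#'
#' Checks structural invariants: positive sizes and rates, an epoch starting
#' at time 0 for every population, strictly positive and topologically
#' consistent split times (a derived population has no epochs older than its
#' split), non-negative migration, and that all populations connect to a
#' single root. Errors name the offending epoch or split.
#'
#' @param model a `demographic_model`.
#' @return the model, invisibly.
#' @export
validate_demographic_model <- function(model) {
  pn <- as.character(model$populations$name)
  P <- length(pn)
  if (any(model$populations$n_diploid < 0))
    stop("negative sampled diploid count")
  if (!is.numeric(model$mu_per_site_per_year) ||
      model$mu_per_site_per_year <= 0)
    stop("mu_per_site_per_year must be > 0")
  if (model$generation_time_years <= 0)
    stop("generation_time_years must be > 0")
  if (!setequal(names(model$epochs), pn))
    stop("epochs must be a named list covering exactly the populations")
  sp <- model$splits
  split_time <- setNames(rep(Inf, P), pn)
  if (nrow(sp)) {
    if (any(sp$time_gen <= 0))
      stop(sprintf("split of '%s' has non-positive time %g",
                   sp$derived[which(sp$time_gen <= 0)[1]],
                   sp$time_gen[which(sp$time_gen <= 0)[1]]))
    if (anyDuplicated(sp$derived))
      stop(sprintf("population '%s' is derived in more than one split",
                   sp$derived[anyDuplicated(sp$derived)]))
    bad <- !(sp$derived %in% pn) | !(sp$ancestral %in% pn)
    if (any(bad))
      stop(sprintf("split references unknown population '%s'",
                   c(sp$derived, sp$ancestral)[!c(sp$derived, sp$ancestral) %in% pn][1]))
    split_time[sp$derived] <- sp$time_gen
    # ancestral population must still exist at the split time
    for (i in seq_len(nrow(sp))) {
      anc <- sp$ancestral[i]
      if (split_time[anc] < sp$time_gen[i])
        stop(sprintf(
          "split at %g merges '%s' into '%s', which itself merged earlier at %g",
          sp$time_gen[i], sp$derived[i], anc, split_time[anc]))
    }
    if (sum(!pn %in% sp$derived) != 1L)
      stop("splits must leave exactly one root population")
  } else if (P > 1 && all(model$migration[upper.tri(model$migration)] == 0) &&
             all(model$migration[lower.tri(model$migration)] == 0)) {
    stop("multiple populations with no splits and no migration can never coalesce")
  }
  for (p in pn) {
    ep <- model$epochs[[p]]
    if (!nrow(ep)) stop(sprintf("population '%s' has no epochs", p))
    if (is.unsorted(ep$start_gen, strictly = TRUE))
      stop(sprintf("epochs of '%s' must have strictly increasing start_gen", p))
    if (ep$start_gen[1] != 0)
      stop(sprintf("first epoch of '%s' must start at 0 (starts at %g)",
                   p, ep$start_gen[1]))
    if (any(ep$ne <= 0))
      stop(sprintf("epoch %d of '%s' has non-positive Ne",
                   which(ep$ne <= 0)[1], p))
    if (any(ep$start_gen >= split_time[p]))
      stop(sprintf("epoch %d of '%s' starts at %g, at or after its split at %g",
                   which(ep$start_gen >= split_time[p])[1], p,
                   ep$start_gen[which(ep$start_gen >= split_time[p])[1]],
                   split_time[p]))
    if (!is.null(ep$growth) &&
        !all(ep$growth %in% c("constant", "exponential")))
      stop(sprintf("unknown growth mode in epochs of '%s'", p))
  }
  if (any(model$migration < 0)) stop("migration rates must be >= 0")
  invisible(model)
}

#' Per-generation mutation rate of a model
#' @param model a `demographic_model`.
#' @return mutation rate per site per generation.
#' @export
mu_per_generation <- function(model) {
  model$mu_per_site_per_year * model$generation_time_years
}

#' Default four-population study demography
#'
#' An isolation-with-migration model for four geographic groups of a highly
#' inbreeding plant: a western lineage (WES) splitting from the ancestor of
#' three eastern groups (COL, UTA, NOR) at 89,500 generations (179 thousand
#' years at a 2-year generation time), COL splitting at 35,000 generations
#' and UTA/NOR at 15,000 generations. Ancestral diploid sizes are 24,000
#' (root), 36,000 (eastern ancestor) and 39,000 (UTA+NOR ancestor);
#' post-split sizes 19,000 / 100,000 / 110,000 / 11,000 for
#' WES / COL / UTA / NOR. Migration is symmetric and weak (1e-6 per
#' generation). Mutation clock: 7e-9 substitutions per site per year, 2-year
#' generations.
#'
#' @param n_diploid sampled diploid individuals per population (length 1 or 4).
#' @return a `demographic_model`.
#' @export
default_demography <- function(n_diploid = 10) {
  pops <- c("WES", "COL", "UTA", "NOR")
  if (length(n_diploid) == 1L) n_diploid <- rep(n_diploid, 4L)
  demographic_model(
    populations = data.frame(name = pops, n_diploid = n_diploid),
    epochs = list(
      WES = data.frame(start_gen = c(0, 89500), ne = c(19000, 24000)),
      COL = data.frame(start_gen = c(0, 35000), ne = c(100000, 36000)),
      UTA = data.frame(start_gen = c(0, 15000), ne = c(110000, 39000)),
      NOR = data.frame(start_gen = 0, ne = 11000)),
    splits = data.frame(
      time_gen = c(15000, 35000, 89500),
      derived = c("NOR", "UTA", "COL"),
      ancestral = c("UTA", "COL", "WES")),
    migration = 1e-6,
    mu_per_site_per_year = 7e-9,
    generation_time_years = 2)
}

# Expand exponential-growth epochs into piecewise-constant steps for the
# C++ core.  An exponential epoch interpolates log-linearly from its own Ne
# at its start to the next (older) epoch's Ne.
expand_epochs <- function(ep, n_steps = 32L) {
  if (is.null(ep$growth) || !any(ep$growth == "exponential")) return(ep)
  out <- list()
  for (i in seq_len(nrow(ep))) {
    if (!identical(ep$growth[i], "exponential") || i == nrow(ep)) {
      out[[length(out) + 1L]] <-
        data.frame(start_gen = ep$start_gen[i], ne = ep$ne[i])
      next
    }
    t0 <- ep$start_gen[i]; t1 <- ep$start_gen[i + 1]
    n0 <- ep$ne[i]; n1 <- ep$ne[i + 1]
    ts <- seq(t0, t1, length.out = n_steps + 1L)[-(n_steps + 1L)]
    ns <- exp(seq(log(n0), log(n1), length.out = n_steps + 1L))[-(n_steps + 1L)]
    out[[length(out) + 1L]] <- data.frame(start_gen = ts, ne = ns)
  }
  do.call(rbind, out)
}

# Flatten a model into the argument set of the C++ simulator.
model_to_cpp_args <- function(model, sample_haploids = NULL) {
  pn <- as.character(model$populations$name)
  P <- length(pn)
  if (is.null(sample_haploids)) sample_haploids <- 2L * model$populations$n_diploid
  ed <- integer(0); es <- numeric(0); en <- numeric(0)
  for (p in seq_len(P)) {
    ep <- expand_epochs(model$epochs[[pn[p]]])
    ed <- c(ed, rep(p - 1L, nrow(ep)))
    es <- c(es, ep$start_gen)
    en <- c(en, ep$ne)
  }
  sp <- model$splits
  list(sample_sizes = as.integer(sample_haploids),
       epoch_deme = as.integer(ed), epoch_start = es, epoch_ne = en,
       split_time = as.numeric(sp$time_gen),
       split_derived = as.integer(match(sp$derived, pn) - 1L),
       split_ancestral = as.integer(match(sp$ancestral, pn) - 1L),
       mig = unname(as.matrix(model$migration)))
}
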