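#' Define a demographic scenario
#'
#' A scenario is a set of constant-size populations related by population
#' splits (merges looking backward in time) and instantaneous admixture
#' pulses.  Time is measured backward in generations from the sampling
#' time; `Ne` is the diploid effective size.  At equal event times pulses
#' are applied before merges, so a hybrid population can be specified as a
#' pulse from one parent immediately followed by a merge into the other.
#'
#' @param populations data.frame with columns `name`, `n_diploid` (sampled
#'   diploid individuals; 0 for ancestral/unsampled populations) and `ne`
#'   (diploid effective size).
#' @param splits data.frame with columns `time`, `derived`, `ancestral`:
#'   backward in time, at `time` all lineages of `derived` move into
#'   `ancestral` and `derived` becomes inactive.
#' @param pulses optional data.frame with columns `time`, `recipient`,
#'   `donor`, `alpha`: backward in time each lineage in `recipient` moves
#'   to `donor` with probability `alpha`.
#' @param generation_years years per generation, used only when converting
#'   calendar times at configuration boundaries (default 11.7, a pinniped
#'   generation length).
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(populations, splits,
                                 pulses = NULL, generation_years = 11.7) {
  stopifnot(is.data.frame(populations),
            all(c("name", "n_diploid", "ne") %in% names(populations)))
  if (anyDuplicated(populations$name))
    stop("population names must be unique")
  if (any(populations$ne <= 0)) stop("Ne must be positive")
  if (sum(populations$n_diploid) < 1) stop("at least one sampled individual")
  if (is.null(pulses))
    pulses <- data.frame(time = numeric(), recipient = character(),
                         donor = character(), alpha = numeric())
  stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
  if (nrow(pulses) > 0) {
    stopifnot(all(c("time", "recipient", "donor", "alpha") %in% names(pulses)))
    if (any(pulses$alpha < 0 | pulses$alpha > 1))
      stop("pulse proportions must lie in [0, 1]")
  }
  if (any(c(splits$time, pulses$time) <= 0))
    stop("event times must be strictly positive")
  refd <- c(splits$derived, splits$ancestral, pulses$recipient, pulses$donor)
  if (!all(refd %in% populations$name))
    stop("event references unknown population(s): ",
         paste(setdiff(refd, populations$name), collapse = ", "))
  obj <- structure(list(populations = populations, splits = splits,
                        pulses = pulses, generation_years = generation_years),
                   class = "demographic_scenario")
  validate_scenario(obj)
  obj
}

# event matrix for the C++ engine: (time, type, a, b, alpha) sorted by
# time with pulses (type 0) before merges (type 1) at ties
scenario_events <- function(scenario) {
  pops <- scenario$populations$name
  idx <- setNames(seq_along(pops), pops)
  sp <- scenario$splits
  pu <- scenario$pulses
  ev <- rbind(
    if (nrow(pu) > 0)
      cbind(pu$time, 0, idx[pu$recipient], idx[pu$donor], pu$alpha),
    if (nrow(sp) > 0)
      cbind(sp$time, 1, idx[sp$derived], idx[sp$ancestral], 0)
  )
  if (is.null(ev)) ev <- matrix(numeric(), ncol = 5)
  ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
}

# checks the structural invariants: each population is derived at most
# once, pulse participants are alive at the pulse time, and exactly one
# population survives all merges (so every lineage can reach a common
# ancestor)
validate_scenario <- function(scenario) {
  pops <- scenario$populations$name
  sp <- scenario$splits
  if (anyDuplicated(sp$derived))
    stop("a population can be the derived side of at most one split")
  death <- setNames(rep(Inf, length(pops)), pops)
  death[sp$derived] <- sp$time
  pu <- scenario$pulses
  if (nrow(pu) > 0) {
    ok <- pu$time <= death[pu$recipient] & pu$time <= death[pu$donor]
    if (!all(ok))
      stop("pulse at a time when recipient or donor is no longer active")
  }
  roots <- setdiff(pops, sp$derived)
  if (length(roots) != 1)
    stop("scenario must resolve to a single root population; found: ",
         paste(roots, collapse = ", "))
  # every merge target must still be alive when it receives lineages
  if (nrow(sp) > 0 && any(sp$time > death[sp$ancestral]))
    stop("split into a population that is no longer active")
  invisible(TRUE)
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("<demographic_scenario> ", nrow(x$populations), " populations, ",
      nrow(x$splits), " splits, ", nrow(x$pulses), " pulses\n", sep = "")
  samp <- x$populations[x$populations$n_diploid > 0, ]
  cat("  sampled:",
      paste(sprintf("%s (%d dip, Ne %g)", samp$name, samp$n_diploid, samp$ne),
            collapse = ", "), "\n")
  invisible(x)
}

#' Convert years to generations
#' @param years time in years
#' @param generation_years years per generation (default 11.7)
#' @return time in generations, rounded to the nearest integer
#' @export
years_to_generations <- function(years, generation_years = 11.7) {
  round(years / generation_years)
}

#' Five-taxon fur seal demographic history
#'
#' The default history emulated by the synthetic-data generator: the
#' Antarctic fur seal (Afs) as outgroup splitting 2.4 Ma; the New Zealand
#' fur seal (NZfs) at 1.5 Ma; the Galapagos (Gfs) / South American (SAfs)
#' split at 0.64 Ma; and the Peruvian fur seal (Pfs) originating 0.43 Ma
#' as an instantaneous hybrid with 67% Gfs and 33% SAfs ancestry.  The
#' SAfs is represented by two demes (`SAfs_AR`, `SAfs_FK`) whose split
#' predates the hybrid origin, so that f4-ratio configurations with a
#' within-species sister lineage of the donor are admissible.  All times
#' are converted to generations at 11.7 years/generation.
#'
#' The hybrid lineage gets a larger default Ne than the other branches:
#' an admixed genome that still shows strong topology discordance and a
#' clearly negative f3 tens of thousands of generations after its origin
#' must have experienced little post-origin drift, which a constant-size
#' coalescent emulates with a large effective size.
#'
#' @param ne diploid effective size of the non-hybrid branches (default
#'   10000).
#' @param ne_pfs diploid effective size of the hybrid lineage (default
#'   150000; see Details).
#' @param n_diploid sampled diploids per terminal population (default 2).
#' @param alpha_gfs Gfs ancestry proportion of the Pfs (default 0.67).
#' @param deme_split_gen split time (generations) of the two SAfs demes
#'   (default 45000, before the ~36750-generation hybrid origin).
#' @return A [demographic_scenario()].
#' @export
fur_seal_history <- function(ne = 10000, ne_pfs = 150000, n_diploid = 2,
                             alpha_gfs = 0.67, deme_split_gen = 45000) {
  gy <- 11.7
  t_root <- years_to_generations(2.4e6, gy)   # Afs vs rest
  t_nz   <- years_to_generations(1.5e6, gy)   # NZfs
  t_gs   <- years_to_generations(0.64e6, gy)  # Gfs/SAfs
  t_h    <- years_to_generations(0.43e6, gy)  # Pfs hybrid origin
  pops <- data.frame(
    name = c("Afs", "NZfs", "Gfs", "SAfs_AR", "SAfs_FK", "Pfs"),
    n_diploid = c(n_diploid, n_diploid, n_diploid, n_diploid, n_diploid,
                  n_diploid),
    ne = c(ne, ne, ne, ne, ne, ne_pfs))
  splits <- data.frame(
    time = c(deme_split_gen, t_h, t_gs, t_nz, t_root),
    derived = c("SAfs_FK", "Pfs", "SAfs_AR", "Gfs", "NZfs"),
    ancestral = c("SAfs_AR", "Gfs", "Gfs", "NZfs", "Afs"))
  pulses <- data.frame(time = t_h, recipient = "Pfs", donor = "SAfs_AR",
                       alpha = 1 - alpha_gfs)
  demographic_scenario(pops, splits, pulses, generation_years = gy)
}
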