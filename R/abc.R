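#' Prior specification for the hybrid-origin scenario test
#'
#' Uniform priors for the four demographic scenarios compared by the ABC
#' test.  Times are given in years and converted to generations at
#' `generation_years`.  The hybridization time prior spans the externally
#' estimated confidence interval for the hybrid origin (0.40-0.46 Ma by
#' default) and the parental divergence prior +/-10% around 0.64 Ma.
#' Offshoot-subpopulation sizes get the narrower bound (10-10,000) and
#' the offshoot durations `Tg`/`Ts` are drawn between the structural
#' minimum `m` and `Tdiv - Th`.
#'
#' @param m minimum duration (generations) of the intermediate
#'   subpopulations in the non-instantaneous scenarios; the discriminating
#'   constraint of the test (typical values 0, 100, 300)
#' @param th_yr,tdiv_yr hybridization and parental-divergence time bounds
#'   in years
#' @param ne_extant,ne_offshoot,ne_hybrid diploid Ne bounds
#' @param alpha bounds of the Gfs-ancestry proportion of the hybrid
#' @param generation_years years per generation (default 11.7)
#' @return An object of class `abc_priors`.
#' @export
abc_priors <- function(m = 100,
                       th_yr = c(0.40e6, 0.46e6),
                       tdiv_yr = 0.64e6 * c(0.9, 1.1),
                       ne_extant = c(100, 100000),
                       ne_offshoot = c(10, 10000),
                       ne_hybrid = c(100, 100000),
                       alpha = c(0.05, 0.95),
                       generation_years = 11.7) {
  pr <- list(
    th = years_to_generations(th_yr, generation_years),
    tdiv = years_to_generations(tdiv_yr, generation_years),
    ne_extant = ne_extant, ne_offshoot = ne_offshoot,
    ne_hybrid = ne_hybrid, alpha = alpha, m = m,
    generation_years = generation_years)
  for (nm in c("th", "tdiv", "ne_extant", "ne_offshoot", "ne_hybrid",
               "alpha")) {
    b <- pr[[nm]]
    if (!all(is.finite(b)) || b[1] >= b[2])
      stop("prior bounds for ", nm, " must be finite with lower < upper")
  }
  if (pr$th[2] >= pr$tdiv[1])
    stop("unsatisfiable ordering: Th upper bound must be below Tdiv ",
         "lower bound")
  if (pr$tdiv[1] - pr$th[2] <= m)
    stop("unsatisfiable: minimum duration m leaves no room for Tg/Ts")
  structure(pr, class = "abc_priors")
}

#' Build the four hybrid-origin scenario templates
#'
#' Scenario 1 is the instantaneous hybrid origin: the Pfs arises at `Th`
#' from a Gfs/SAfs cross (proportion `alpha` from Gfs) with no prior
#' subpopulation structure.  Scenario 2 derives the Pfs from a SAfs
#' offshoot (alive for `Tg` generations) that receives a Gfs pulse at
#' `Th`; scenario 3 is the mirror image (Gfs offshoot, SAfs pulse, `Ts`);
#' scenario 4 fuses a Gfs offshoot and a SAfs offshoot at `Th`.
#'
#' @param priors an [abc_priors()]
#' @param n_diploid sampled diploids per extant population (default 2)
#' @return List of 4 `scenario_template`s, each with elements `id`,
#'   `label`, `param_names`, `draw(priors)` and `build(params)`.
#' @export
build_scenarios <- function(priors, n_diploid = 2) {
  stopifnot(inherits(priors, "abc_priors"))
  base_names <- c("th", "tdiv", "ne_gfs", "ne_safs", "ne_anc", "ne_pfs",
                  "alpha")
  draw_base <- function(priors) {
    c(th = runif(1, priors$th[1], priors$th[2]),
      tdiv = runif(1, priors$tdiv[1], priors$tdiv[2]),
      ne_gfs = runif(1, priors$ne_extant[1], priors$ne_extant[2]),
      ne_safs = runif(1, priors$ne_extant[1], priors$ne_extant[2]),
      ne_anc = runif(1, priors$ne_extant[1], priors$ne_extant[2]),
      ne_pfs = runif(1, priors$ne_hybrid[1], priors$ne_hybrid[2]),
      alpha = runif(1, priors$alpha[1], priors$alpha[2]))
  }
  draw_dur <- function(priors, p) runif(1, priors$m, p["tdiv"] - p["th"])
  draw_off <- function(priors) runif(1, priors$ne_offshoot[1],
                                     priors$ne_offshoot[2])
  pops_base <- function(p, extra = NULL) {
    rbind(data.frame(name = c("Gfs", "SAfs", "Pfs", "ANC"),
                     n_diploid = c(n_diploid, n_diploid, n_diploid, 0),
                     ne = unname(c(p["ne_gfs"], p["ne_safs"], p["ne_pfs"],
                                   p["ne_anc"]))),
          extra)
  }
  root_splits <- function(p) {
    data.frame(time = c(p[["tdiv"]], p[["tdiv"]]),
               derived = c("SAfs", "Gfs"), ancestral = c("ANC", "ANC"))
  }
  # raw encodings for the reference-table hot path: population order is
  # Gfs, SAfs, Pfs, ANC [, OFF_G, OFF_S]; events are (time, type, a, b,
  # alpha) rows sorted by (time, pulses-before-merges), exactly what
  # scenario_events() would produce for build()
  ns <- as.integer(2 * n_diploid)
  raw <- function(p, extra_ne = NULL, ev) {
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    list(nsam = c(ns, ns, ns, 0L, integer(length(extra_ne))),
         ne = unname(c(p["ne_gfs"], p["ne_safs"], p["ne_pfs"],
                       p["ne_anc"], extra_ne)),
         ev = ev)
  }
  G <- 1; S <- 2; P <- 3; ANC <- 4
  tmpl <- list(
    list(id = 1L, label = "instantaneous hybrid origin",
         param_names = base_names,
         build_raw = function(p) raw(p, NULL, rbind(
           c(p[["th"]], 0, P, S, 1 - p[["alpha"]]),
           c(p[["th"]], 1, P, G, 0),
           c(p[["tdiv"]], 1, S, ANC, 0),
           c(p[["tdiv"]], 1, G, ANC, 0))),
         draw = function(priors) draw_base(priors),
         build = function(p) demographic_scenario(
           pops_base(p),
           rbind(data.frame(time = p[["th"]], derived = "Pfs",
                            ancestral = "Gfs"),
                 root_splits(p)),
           data.frame(time = p[["th"]], recipient = "Pfs", donor = "SAfs",
                      alpha = 1 - p[["alpha"]]))),
    list(id = 2L, label = "SAfs offshoot + Gfs introgression",
         param_names = c(base_names, "tg", "ne_off_s"),
         build_raw = function(p) raw(p, p[["ne_off_s"]], rbind(
           c(p[["th"]], 0, P, G, p[["alpha"]]),
           c(p[["th"]], 1, P, 5, 0),
           c(p[["th"]] + p[["tg"]], 1, 5, S, 0),
           c(p[["tdiv"]], 1, S, ANC, 0),
           c(p[["tdiv"]], 1, G, ANC, 0))),
         draw = function(priors) {
           p <- draw_base(priors)
           c(p, tg = draw_dur(priors, p), ne_off_s = draw_off(priors))
         },
         build = function(p) demographic_scenario(
           pops_base(p, data.frame(name = "OFF_S", n_diploid = 0,
                                   ne = p[["ne_off_s"]])),
           rbind(data.frame(time = c(p[["th"]], p[["th"]] + p[["tg"]]),
                            derived = c("Pfs", "OFF_S"),
                            ancestral = c("OFF_S", "SAfs")),
                 root_splits(p)),
           data.frame(time = p[["th"]], recipient = "Pfs", donor = "Gfs",
                      alpha = p[["alpha"]]))),
    list(id = 3L, label = "Gfs offshoot + SAfs introgression",
         param_names = c(base_names, "ts", "ne_off_g"),
         build_raw = function(p) raw(p, p[["ne_off_g"]], rbind(
           c(p[["th"]], 0, P, S, 1 - p[["alpha"]]),
           c(p[["th"]], 1, P, 5, 0),
           c(p[["th"]] + p[["ts"]], 1, 5, G, 0),
           c(p[["tdiv"]], 1, S, ANC, 0),
           c(p[["tdiv"]], 1, G, ANC, 0))),
         draw = function(priors) {
           p <- draw_base(priors)
           c(p, ts = draw_dur(priors, p), ne_off_g = draw_off(priors))
         },
         build = function(p) demographic_scenario(
           pops_base(p, data.frame(name = "OFF_G", n_diploid = 0,
                                   ne = p[["ne_off_g"]])),
           rbind(data.frame(time = c(p[["th"]], p[["th"]] + p[["ts"]]),
                            derived = c("Pfs", "OFF_G"),
                            ancestral = c("OFF_G", "Gfs")),
                 root_splits(p)),
           data.frame(time = p[["th"]], recipient = "Pfs", donor = "SAfs",
                      alpha = 1 - p[["alpha"]]))),
    list(id = 4L, label = "fusion of two offshoots",
         param_names = c(base_names, "tg", "ts", "ne_off_g", "ne_off_s"),
         build_raw = function(p) raw(
           p, c(p[["ne_off_g"]], p[["ne_off_s"]]), rbind(
             c(p[["th"]], 0, P, 6, 1 - p[["alpha"]]),
             c(p[["th"]], 1, P, 5, 0),
             c(p[["th"]] + p[["ts"]], 1, 5, G, 0),
             c(p[["th"]] + p[["tg"]], 1, 6, S, 0),
             c(p[["tdiv"]], 1, S, ANC, 0),
             c(p[["tdiv"]], 1, G, ANC, 0))),
         draw = function(priors) {
           p <- draw_base(priors)
           c(p, tg = draw_dur(priors, p), ts = draw_dur(priors, p),
             ne_off_g = draw_off(priors), ne_off_s = draw_off(priors))
         },
         build = function(p) demographic_scenario(
           pops_base(p, data.frame(name = c("OFF_G", "OFF_S"),
                                   n_diploid = 0,
                                   ne = unname(c(p[["ne_off_g"]],
                                                 p[["ne_off_s"]])))),
           rbind(data.frame(
             time = c(p[["th"]], p[["th"]] + p[["ts"]],
                      p[["th"]] + p[["tg"]]),
             derived = c("Pfs", "OFF_G", "OFF_S"),
             ancestral = c("OFF_G", "Gfs", "SAfs")),
             root_splits(p)),
           data.frame(time = p[["th"]], recipient = "Pfs", donor = "OFF_S",
                      alpha = 1 - p[["alpha"]]))))
  lapply(tmpl, function(x) structure(x, class = "scenario_template"))
}

#' Mid-prior parameter values for a scenario template
#' @param template a `scenario_template`
#' @param priors an [abc_priors()]
#' @return Named vector of parameter midpoints (durations at the midpoint
#'   of their conditional range).
#' @export
mid_prior_params <- function(template, priors) {
  p <- c(th = mean(priors$th), tdiv = mean(priors$tdiv),
         ne_gfs = mean(priors$ne_extant), ne_safs = mean(priors$ne_extant),
         ne_anc = mean(priors$ne_extant), ne_pfs = mean(priors$ne_hybrid),
         alpha = mean(priors$alpha))
  extra <- setdiff(template$param_names, names(p))
  for (nm in extra) {
    p[nm] <- if (nm %in% c("tg", "ts"))
      mean(c(priors$m, p[["tdiv"]] - p[["th"]]))
    else mean(priors$ne_offshoot)
  }
  p[template$param_names]
}

# all parameter columns a reference table can hold
abc_param_columns <- c("th", "tdiv", "ne_gfs", "ne_safs", "ne_anc",
                       "ne_pfs", "alpha", "tg", "ts", "ne_off_g",
                       "ne_off_s")

#' Summary statistics of a three-population SNP panel
#'
#' The fixed 26-statistic vector used by the ABC machinery, patterned on
#' the one-, two- and three-sample statistics of SNP-based ABC reference
#' software: per-population expected heterozygosity (3) and proportion of
#' monomorphic sites (3); pairwise Hudson FST (3), Nei standard genetic
#' distance (3), and the across-site variance of the squared frequency
#' difference (3); f3(hybrid; parent1, parent2) and its across-site
#' variance (2); the mean and variance of the per-site within-population
#' allele frequency (6); and the kurtosis of the per-site frequency
#' difference between the hybrid and each parent plus between the parents
#' (3).  The higher-moment statistics are what separates drift that acted
#' on only one ancestry component of an admixed genome (an offshoot
#' bottleneck) from genome-wide drift, which first-moment statistics
#' cannot distinguish.
#'
#' @param panel a [snp_panel()] containing the three scenario populations
#' @param hybrid,parents population labels (defaults `Pfs` and
#'   `c("Gfs", "SAfs")`)
#' @return Named numeric vector of length 26.
#' @export
summarize_panel <- function(panel, hybrid = "Pfs",
                            parents = c("Gfs", "SAfs")) {
  stopifnot(inherits(panel, "snp_panel"))
  pops <- c(parents, hybrid)
  if (!all(pops %in% populations(panel)))
    stop("panel lacks population(s): ",
         paste(setdiff(pops, populations(panel)), collapse = ", "))
  ft <- compute_freqs(panel)
  if (nrow(ft$freq) == 0) stop("no segregating sites")
  f <- ft$freq[, pops, drop = FALSE]
  n <- ft$count[, pops, drop = FALSE]
  if (all(f == 0 | f == 1, na.rm = TRUE)) stop("no segregating sites")
  summarize_freqs(f, n, pops)
}

# statistics kernel shared by summarize_panel() and the reference-table
# hot path: f and n are sites x 3 matrices (parent1, parent2, hybrid)
summarize_freqs <- function(f, n, pops) {
  het <- vapply(1:3, function(j) {
    ok <- !is.na(n[, j]) & n[, j] > 1
    mean((n[ok, j] / (n[ok, j] - 1)) * 2 * f[ok, j] * (1 - f[ok, j]))
  }, numeric(1))
  mono <- colMeans(f == 0 | f == 1, na.rm = TRUE)

  pair_idx <- list(c(1, 2), c(1, 3), c(2, 3))
  fst <- nei <- vardiff <- kdiff <- numeric(3)
  for (k in 1:3) {
    i <- pair_idx[[k]][1]; j <- pair_idx[[k]][2]
    p1 <- f[, i]; p2 <- f[, j]; n1 <- n[, i]; n2 <- n[, j]
    ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
    num <- (p1[ok] - p2[ok])^2 -
      p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
      p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
    den <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
    sden <- sum(den)
    fst[k] <- if (abs(sden) < 1e-12) 0 else sum(num) / sden
    nei[k] <- nei_distance(p1, p2)
    dd <- p1 - p2
    vardiff[k] <- var(dd^2, na.rm = TRUE)
    x <- dd[!is.na(dd)]
    m2 <- mean((x - mean(x))^2)
    kdiff[k] <- if (m2 == 0) 0 else mean((x - mean(x))^4) / m2^2
  }
  f3site <- (f[, 3] - f[, 1]) * (f[, 3] - f[, 2])
  sfs_mean <- colMeans(f, na.rm = TRUE)
  sfs_var <- apply(f, 2, var, na.rm = TRUE)

  pair_lab <- vapply(pair_idx, function(ij)
    paste(pops[ij], collapse = "_"), character(1))
  setNames(c(het, mono, fst, nei, vardiff, kdiff,
             mean(f3site, na.rm = TRUE), var(f3site, na.rm = TRUE),
             sfs_mean, sfs_var),
           c(paste0("het_", pops), paste0("mono_", pops),
             paste0("fst_", pair_lab), paste0("nei_", pair_lab),
             paste0("vardiff_", pair_lab), paste0("kurt_", pair_lab),
             "f3_hybrid", "f3_var",
             paste0("sfsmean_", pops), paste0("sfsvar_", pops)))
}

# Nei (1972) standard genetic distance from biallelic frequencies
nei_distance <- function(p1, p2) {
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  jxy <- mean(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- mean(p1^2 + (1 - p1)^2)
  jy <- mean(p2^2 + (1 - p2)^2)
  -log(jxy / sqrt(jx * jy))
}

#' Simulate an ABC reference table
#'
#' Draws `n_per_scenario` parameter vectors per scenario from the priors,
#' simulates an unlinked SNP panel for each, and stores the summary
#' statistics.  Per-draw seeds are derived deterministically from the
#' master seed (XOR with scenario id and draw index), so tables are
#' reproducible.
#'
#' @param templates list of `scenario_template`s from [build_scenarios()]
#' @param priors an [abc_priors()]
#' @param n_per_scenario simulations per scenario (warn below 1000)
#' @param n_sites unlinked SNPs per simulated panel
#' @param seed master seed
#' @return An `abc_reference`: list with `stats` (N x 16 matrix),
#'   `params` (N-row data.frame, `NA` for parameters a scenario lacks),
#'   `scenario` (integer labels), standardization `center`/`scale`, and
#'   the generating `templates`, `priors`, `n_sites`.
#' @export
simulate_reference <- function(templates, priors, n_per_scenario, n_sites,
                               seed) {
  if (n_per_scenario < 100) stop("n_per_scenario must be at least 100")
  if (n_per_scenario < 1000)
    warning("fewer than 1000 simulations per scenario: posteriors will ",
            "be noisy")
  N <- n_per_scenario * length(templates)
  stats <- NULL
  params <- as.data.frame(matrix(NA_real_, N, length(abc_param_columns),
                                 dimnames = list(NULL, abc_param_columns)))
  scen <- integer(N)
  row <- 0L
  pops <- c("Gfs", "SAfs", "Pfs")
  for (tm in templates) {
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      ds <- abc_draw_seed(seed, tm$id, i)
      set.seed(ds)
      p <- tm$draw(priors)
      # hot path: raw event encoding and direct frequency computation,
      # numerically identical to simulate_panel() + summarize_panel()
      rw <- tm$build_raw(p)
      set.seed(ds)
      H <- .sim_sites_cpp(rw$nsam, rw$ne, rw$ev, as.integer(n_sites))
      nh <- rw$nsam[1]  # haploids per sampled population
      f <- vapply(1:3, function(k)
        rowSums(H[, ((k - 1) * nh + 1):(k * nh), drop = FALSE]) / nh,
        numeric(n_sites))
      if (!is.matrix(f)) f <- matrix(f, ncol = 3)
      n_mat <- matrix(nh, n_sites, 3)
      s <- summarize_freqs(f, n_mat, pops)
      if (is.null(stats))
        stats <- matrix(NA_real_, N, length(s),
                        dimnames = list(NULL, names(s)))
      stats[row, ] <- s
      params[row, names(p)] <- p
      scen[row] <- tm$id
    }
  }
  structure(list(stats = stats, params = params, scenario = scen,
                 center = colMeans(stats), scale = apply(stats, 2, sd),
                 templates = templates, priors = priors,
                 n_sites = n_sites, seed = seed),
            class = "abc_reference")
}

abc_draw_seed <- function(seed, scenario_id, draw_index) {
  bitwAnd(bitwXor(as.integer(seed),
                  as.integer(scenario_id) * 1048576L +
                    as.integer(draw_index)), 2147483647L)
}

#' @export
print.abc_reference <- function(x, ...) {
  cat("<abc_reference> ", nrow(x$stats), " simulations (",
      paste(table(x$scenario), collapse = "/"), " per scenario), ",
      x$n_sites, " sites each\n", sep = "")
  invisible(x)
}

# standardize a statistics matrix by the reference table's constants,
# dropping zero-variance columns
abc_standardize <- function(ref, stats) {
  keep <- ref$scale > 0
  if (!all(keep))
    warning("dropping constant summary statistic(s): ",
            paste(names(ref$scale)[!keep], collapse = ", "))
  sweep(sweep(stats[, keep, drop = FALSE], 2, ref$center[keep]),
        2, ref$scale[keep], "/")
}

#' ABC model choice by rejection and logistic regression
#'
#' Standardizes the summary statistics by the reference table's column
#' means and SDs, ranks simulations by Euclidean distance to the observed
#' vector, and retains the closest fraction (default 1%).  The direct
#' (rejection) posterior is each scenario's share of the retained set.
#' The logistic posterior follows the standard two-step procedure for
#' SNP-scale reference tables: the statistics are first projected onto
#' the linear discriminant axes of the scenario labels (computed from the
#' full reference table), and a distance-weighted (Epanechnikov)
#' multinomial logistic regression of the label on those axes, fitted to
#' the retained set, is evaluated at the observed point.  The projection
#' keeps the local regression well-conditioned; a raw regression on all
#' statistics would have more parameters than retained simulations.  A
#' bootstrap over the retained set gives the confidence interval.
#'
#' @param ref an `abc_reference`
#' @param observed named summary-statistic vector (from
#'   [summarize_panel()])
#' @param retain_fraction fraction of simulations retained (default 0.01)
#' @param n_boot bootstrap replicates for the CI (default 100; 0 skips)
#' @return A `model_posterior` data.frame: scenario, `direct`,
#'   `logistic`, `ci_lo`, `ci_hi`; `attr(, "n_retained")` is the retained
#'   set size.
#' @export
model_choice <- function(ref, observed, retain_fraction = 0.01,
                         n_boot = 100) {
  stopifnot(inherits(ref, "abc_reference"),
            retain_fraction > 0, retain_fraction <= 1)
  S <- abc_standardize(ref, ref$stats)
  obs <- abc_standardize(ref, matrix(observed[colnames(ref$stats)], 1,
                                     dimnames = list(NULL,
                                                     colnames(ref$stats))))
  d <- sqrt(rowSums(sweep(S, 2, obs[1, ])^2))
  n_keep <- ceiling(retain_fraction * nrow(S))
  idx <- order(d)[seq_len(n_keep)]
  scen_levels <- sort(unique(ref$scenario))
  lab <- factor(ref$scenario[idx], levels = scen_levels)
  direct <- as.numeric(table(lab)) / n_keep

  present <- levels(droplevels(lab))
  if (length(present) < length(scen_levels))
    warning("scenario(s) ", paste(setdiff(scen_levels, present),
                                  collapse = ", "),
            " absent from the retained set; their posterior is 0")
  # discriminant axes from the full table; retained set projected on them
  ld <- MASS::lda(S, grouping = factor(ref$scenario))
  L <- S %*% ld$scaling
  obs_l <- obs %*% ld$scaling
  dmax <- max(d[idx])
  epan <- function(dd) {
    w <- if (dmax > 0) 1 - (dd / dmax)^2 else rep(1, length(dd))
    pmax(w, 1e-6)
  }
  fit_predict <- function(rows) {
    l <- droplevels(factor(ref$scenario[rows], levels = scen_levels))
    if (nlevels(l) == 1)
      return(setNames(as.numeric(scen_levels == levels(l)),
                      scen_levels))
    dat <- as.data.frame(L[rows, , drop = FALSE])
    dat$.label <- l
    dat$.w <- epan(d[rows])
    fit <- nnet::multinom(.label ~ . - .w, data = dat, weights = .w,
                          trace = FALSE, maxit = 500, MaxNWts = 5000)
    nd <- as.data.frame(obs_l)
    nd$.w <- 1
    pr <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr)) && nlevels(l) == 2)
      pr <- setNames(c(1 - pr, pr), levels(l))
    full <- setNames(numeric(length(scen_levels)), scen_levels)
    full[names(pr)] <- pr
    full
  }
  logistic <- fit_predict(idx)
  ci <- matrix(NA_real_, length(scen_levels), 2)
  if (n_boot > 0) {
    boots <- replicate(n_boot,
                       fit_predict(sample(idx, n_keep, replace = TRUE)))
    ci <- t(apply(boots, 1, quantile, probs = c(0.025, 0.975)))
  }
  out <- data.frame(scenario = scen_levels, direct = direct,
                    logistic = as.numeric(logistic),
                    ci_lo = ci[, 1], ci_hi = ci[, 2])
  attr(out, "n_retained") <- n_keep
  class(out) <- c("model_posterior", "data.frame")
  out
}

# weighted quantiles (type-7-like interpolation on the weighted CDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Posterior distribution of scenario parameters
#'
#' Rejection-based parameter estimation for one scenario: simulations of
#' that scenario are ranked by distance to the observed statistics, the
#' closest fraction is retained, and retained draws are weighted with an
#' Epanechnikov kernel in the distance.
#'
#' @param ref an `abc_reference`
#' @param observed named summary-statistic vector
#' @param scenario_id scenario whose parameters to estimate
#' @param retain_fraction fraction of that scenario's simulations retained
#' @param params parameter names (default: all the scenario has)
#' @return Named list of `param_posterior` objects, each with `sample`,
#'   `weights`, `quantiles` (2.5/50/97.5%) and `prior_bounds`.
#' @export
estimate_params <- function(ref, observed, scenario_id,
                            retain_fraction = 0.01, params = NULL) {
  stopifnot(inherits(ref, "abc_reference"))
  rows <- which(ref$scenario == scenario_id)
  if (length(rows) == 0) stop("scenario ", scenario_id, " not in table")
  S <- abc_standardize(ref, ref$stats[rows, , drop = FALSE])
  obs <- abc_standardize(ref, matrix(observed[colnames(ref$stats)], 1,
                                     dimnames = list(NULL,
                                                     colnames(ref$stats))))
  d <- sqrt(rowSums(sweep(S, 2, obs[1, ])^2))
  n_keep <- max(2L, ceiling(retain_fraction * length(rows)))
  sel <- order(d)[seq_len(n_keep)]
  dmax <- max(d[sel])
  w <- if (dmax > 0) 1 - (d[sel] / dmax)^2 else rep(1, n_keep)
  w[w <= 0] <- min(w[w > 0]) / 2  # the farthest draw keeps vanishing mass
  tm <- ref$templates[[which(vapply(ref$templates, `[[`, 0L, "id") ==
                               scenario_id)]]
  if (is.null(params)) params <- tm$param_names
  pr_bounds <- abc_prior_bounds(ref$priors)
  out <- lapply(params, function(nm) {
    x <- ref$params[rows[sel], nm]
    structure(list(param = nm, sample = x, weights = w,
                   quantiles = weighted_quantile(x, w,
                                                 c(0.025, 0.5, 0.975)),
                   prior_bounds = pr_bounds[[nm]]),
              class = "param_posterior")
  })
  setNames(out, params)
}

abc_prior_bounds <- function(priors) {
  list(th = priors$th, tdiv = priors$tdiv,
       ne_gfs = priors$ne_extant, ne_safs = priors$ne_extant,
       ne_anc = priors$ne_extant, ne_pfs = priors$ne_hybrid,
       alpha = priors$alpha,
       tg = c(priors$m, priors$tdiv[2] - priors$th[1]),
       ts = c(priors$m, priors$tdiv[2] - priors$th[1]),
       ne_off_g = priors$ne_offshoot, ne_off_s = priors$ne_offshoot)
}

#' @export
print.param_posterior <- function(x, ...) {
  q <- x$quantiles
  cat(sprintf("%s: median %.4g [95%% %.4g, %.4g]\n", x$param, q[2], q[1],
              q[3]))
  invisible(x)
}

#' Posterior-predictive simulations for model checking
#'
#' Resamples retained parameter draws (Epanechnikov-weighted) of one
#' scenario and re-simulates panels under them, yielding the
#' posterior-predictive cloud used by [model_check()].
#'
#' @param ref an `abc_reference`
#' @param observed named summary-statistic vector
#' @param scenario_id scenario to check
#' @param n_sims posterior-predictive simulations (default 100)
#' @param seed integer seed
#' @param retain_fraction fraction retained (default 0.01)
#' @return Matrix of summary statistics, `n_sims` x 16.
#' @export
posterior_predictive <- function(ref, observed, scenario_id, n_sims = 100,
                                 seed = 1L, retain_fraction = 0.01) {
  post <- estimate_params(ref, observed, scenario_id, retain_fraction)
  rows <- which(ref$scenario == scenario_id)
  S <- abc_standardize(ref, ref$stats[rows, , drop = FALSE])
  obs <- abc_standardize(ref, matrix(observed[colnames(ref$stats)], 1,
                                     dimnames = list(NULL,
                                                     colnames(ref$stats))))
  d <- sqrt(rowSums(sweep(S, 2, obs[1, ])^2))
  n_keep <- max(2L, ceiling(retain_fraction * length(rows)))
  sel <- order(d)[seq_len(n_keep)]
  w <- post[[1]]$weights
  tm <- ref$templates[[which(vapply(ref$templates, `[[`, 0L, "id") ==
                               scenario_id)]]
  set.seed(seed)
  pick <- sample(sel, n_sims, replace = TRUE, prob = w)
  seeds <- sample.int(2147483647L, n_sims)
  stats <- NULL
  for (i in seq_len(n_sims)) {
    p <- unlist(ref$params[rows[pick[i]], tm$param_names])
    sim <- simulate_panel(tm$build(p), ref$n_sites, seed = seeds[i])
    s <- summarize_panel(sim$panel)
    if (is.null(stats))
      stats <- matrix(NA_real_, n_sims, length(s),
                      dimnames = list(NULL, names(s)))
    stats[i, ] <- s
  }
  stats
}

#' PCA model checking of an ABC fit
#'
#' Principal axes are computed from the prior-simulated (reference)
#' summary statistics; the prior cloud, the posterior-predictive cloud,
#' and the observed point are projected on PCs 1-2.  The fit is flagged
#' adequate when the observed point falls inside the posterior cloud's
#' 95% Mahalanobis ellipse on those axes.
#'
#' @param ref an `abc_reference` (prior cloud)
#' @param posterior_sims matrix of posterior-predictive statistics, e.g.
#'   from [posterior_predictive()]
#' @param observed named summary-statistic vector
#' @return An `abc_model_check`: list with `prior_coords`,
#'   `posterior_coords`, `observed_coords` (PCs 1-2), `rotation`,
#'   `mahalanobis_d2` and logical `ok`.
#' @export
model_check <- function(ref, posterior_sims, observed) {
  S <- abc_standardize(ref, ref$stats)
  if (ncol(S) < 2) stop("need at least 2 non-constant summary statistics")
  pca <- prcomp(S, center = TRUE, scale. = FALSE)
  proj <- function(m) {
    m <- abc_standardize(ref, m)
    sweep(m, 2, pca$center) %*% pca$rotation[, 1:2, drop = FALSE]
  }
  prior_xy <- pca$x[, 1:2, drop = FALSE]
  post_xy <- proj(posterior_sims[, colnames(ref$stats), drop = FALSE])
  obs_xy <- proj(matrix(observed[colnames(ref$stats)], 1,
                        dimnames = list(NULL, colnames(ref$stats))))
  d2 <- mahalanobis(obs_xy, colMeans(post_xy), stats::cov(post_xy))
  structure(list(prior_coords = prior_xy, posterior_coords = post_xy,
                 observed_coords = obs_xy, rotation = pca$rotation,
                 mahalanobis_d2 = as.numeric(d2),
                 ok = as.numeric(d2) <= qchisq(0.95, 2)),
            class = "abc_model_check")
}

#' @export
print.abc_model_check <- function(x, ...) {
  cat("<abc_model_check> observed Mahalanobis d2 on PCs 1-2: ",
      sprintf("%.2f", x$mahalanobis_d2), " (95% threshold ",
      sprintf("%.2f", qchisq(0.95, 2)), "): ",
      if (x$ok) "model fits the data" else "poor fit", "\n", sep = "")
  invisible(x)
}
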