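#' Build and validate a run configuration
#'
#' Configuration is a flat named list (or a `key = value` text file, see
#' [read_run_config()]).  Recognized keys: `vcf`, `popmap` (input paths;
#' when absent a demonstration panel is simulated under
#' [fur_seal_history()]), `outgroup`, `block_size`, `window_bp`,
#' `n_sites`, `n_windows`, `abc_m`, `abc_n_per_scenario`, `abc_n_sites`,
#' `abc_retain_fraction`, `seed`, `out_dir`, `stages` (comma-separated
#' subset of simulate, fstats, twisst, abc, ploidy).
#'
#' @param config named list of settings
#' @return A validated `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(vcf = NA_character_, popmap = NA_character_,
                   outgroup = "Afs", block_size = 200L,
                   window_bp = 50000L, n_sites = 20000L, n_windows = 200L,
                   abc_m = 100, abc_n_per_scenario = 500L,
                   abc_n_sites = 500L, abc_retain_fraction = 0.02,
                   seed = 1L, out_dir = "hybridscan_out",
                   stages = "simulate,fstats,twisst,ploidy")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (k in c("vcf", "popmap")) {
    if (!is.na(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured ", k, " path does not exist: ", cfg[[k]])
  }
  num <- c("block_size", "window_bp", "n_sites", "n_windows", "abc_m",
           "abc_n_per_scenario", "abc_n_sites", "abc_retain_fraction",
           "seed")
  for (k in num) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$stages <- trimws(strsplit(as.character(cfg$stages), ",")[[1]])
  bad <- setdiff(cfg$stages, c("simulate", "fstats", "twisst", "abc",
                               "ploidy"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read a `key = value` configuration file
#' @param path text file with one `key = value` pair per line; `#` starts
#'   a comment
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  cfg <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  run_config(cfg)
}

output_header <- function(cfg, command) {
  c(sprintf("# hybridscan %s",
            as.character(utils::packageVersion("hybridscan"))),
    sprintf("# command: %s", command),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# seed: %d", as.integer(cfg$seed)))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- cfg[sort(setdiff(names(unclass(cfg)), character(0)))]
  writeLines(paste(names(flat),
                   vapply(flat, function(x) paste(x, collapse = ","), ""),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_with_header <- function(df, path, cfg, command) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg, command), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Run the full hybridscan pipeline
#'
#' Executes the configured stages in order (simulate or load a panel,
#' f-statistics, topology weighting, ABC scenario test, ploidy
#' diagnostics), writing one TSV per stage plus a JSON-like summary, all
#' stamped with the package version, configuration hash and master seed.
#' A single master seed fans out deterministically to the stages, so
#' reruns with an identical configuration are byte-identical.
#'
#' @param config a `run_config` (or plain list passed to [run_config()])
#' @return Invisibly, a list with per-stage results and output paths.
#' @export
run_full <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  res <- list(config = cfg, outputs = character(0))
  t0 <- Sys.time()
  hs_log("run_full started (seed %d)", seed)

  # --- input panel -------------------------------------------------------
  if (!is.na(cfg$vcf)) {
    if (is.na(cfg$popmap)) stop("stage input: vcf given without popmap")
    panel <- read_vcf(cfg$vcf, cfg$popmap)
  } else {
    if (!"simulate" %in% cfg$stages)
      stop("no input VCF configured and the simulate stage is disabled")
    sim <- simulate_panel(fur_seal_history(), cfg$n_sites, seed = seed)
    panel <- sim$panel
  }
  hs_log("panel: %d sites, %d samples", nrow(panel$sites),
         length(panel$samples))
  res$panel <- panel

  # --- f statistics ------------------------------------------------------
  if ("fstats" %in% cfg$stages) {
    ft <- suppressMessages(polarize_by_outgroup(panel, cfg$outgroup))
    blocks <- partition_blocks(nrow(ft$freq), cfg$block_size)
    pops <- setdiff(populations(panel), cfg$outgroup)
    rows <- list()
    for (tri in utils::combn(sort(pops), 3, simplify = FALSE)) {
      r <- f3(ft, tri[1], tri[2], tri[3], blocks)
      rows[[length(rows) + 1]] <- data.frame(
        statistic = "f3", populations = paste(tri[3], ";", tri[1], ",",
                                              tri[2]),
        estimate = r$estimate, se = r$se, z = r$z, n_blocks = r$n_blocks)
    }
    if (length(pops) >= 4) {
      for (qd in utils::combn(sort(pops), 4, simplify = FALSE)) {
        r <- f4(ft, qd[1], qd[2], qd[3], qd[4], blocks)
        rows[[length(rows) + 1]] <- data.frame(
          statistic = "f4",
          populations = paste(qd[1], ",", qd[2], ";", qd[3], ",", qd[4]),
          estimate = r$estimate, se = r$se, z = r$z, n_blocks = r$n_blocks)
      }
    }
    tab <- do.call(rbind, rows)
    p <- file.path(cfg$out_dir, "fstats.tsv")
    write_tsv_with_header(tab, p, cfg, "fstats")
    res$fstats <- tab
    res$outputs <- c(res$outputs, p)
    hs_log("fstats: %d statistics written", nrow(tab))
  }

  # --- topology weighting ------------------------------------------------
  if ("twisst" %in% cfg$stages) {
    sc <- fur_seal_history()
    keep <- c("Afs", "Gfs", "SAfs_AR", "Pfs")
    sc$populations$n_diploid[!sc$populations$name %in% keep] <- 0L
    gt <- simulate_gene_trees(sc, cfg$n_windows, seed = seed + 1L,
                              window_bp = cfg$window_bp)
    tw <- weight_set(gt, outgroup = "Afs")
    p <- file.path(cfg$out_dir, "topology_weights.tsv")
    write_tsv_with_header(as.data.frame(tw), p, cfg, "twisst")
    res$topology_weights <- tw
    res$outputs <- c(res$outputs, p)
    hs_log("twisst: mean weights %s",
           paste(sprintf("%.3f", attr(tw, "mean_weights")), collapse = "/"))
  }

  # --- ABC scenario test -------------------------------------------------
  if ("abc" %in% cfg$stages) {
    priors <- abc_priors(m = cfg$abc_m)
    templates <- build_scenarios(priors)
    obs_sim <- simulate_panel(
      templates[[1]]$build(mid_prior_params(templates[[1]], priors)),
      cfg$abc_n_sites, seed = seed + 2L)
    observed <- summarize_panel(obs_sim$panel)
    ref <- suppressWarnings(
      simulate_reference(templates, priors, cfg$abc_n_per_scenario,
                         cfg$abc_n_sites, seed = seed + 3L))
    set.seed(seed + 4L)
    post <- model_choice(ref, observed, cfg$abc_retain_fraction,
                         n_boot = 50)
    p <- file.path(cfg$out_dir, "abc_posterior.tsv")
    write_tsv_with_header(as.data.frame(post), p, cfg, "abc")
    res$abc <- post
    res$outputs <- c(res$outputs, p)
    hs_log("abc: scenario-1 logistic posterior %.3f", post$logistic[1])
  }

  # --- ploidy ------------------------------------------------------------
  if ("ploidy" %in% cfg$stages) {
    rc <- simulate_read_counts(2, 20000, 30, 0.01, seed = seed + 5L)
    call <- classify_ploidy(allele_balance_histogram(rc))
    tab <- data.frame(candidate = names(call$scores),
                      score = as.numeric(call$scores),
                      called = !is.na(call$ploidy) &
                        call$scores == min(call$scores))
    p <- file.path(cfg$out_dir, "ploidy.tsv")
    write_tsv_with_header(tab, p, cfg, "ploidy")
    res$ploidy <- call
    res$outputs <- c(res$outputs, p)
    hs_log("ploidy: called %s",
           if (is.na(call$ploidy)) "undetermined" else call$ploidy)
  }

  # --- summary -----------------------------------------------------------
  summary_lines <- c(
    output_header(cfg, "run_full"),
    sprintf("# elapsed_s: %.1f", as.numeric(Sys.time() - t0, units = "secs")),
    sprintf("stages: %s", paste(cfg$stages, collapse = ",")),
    sprintf("outputs: %s", paste(res$outputs, collapse = ",")))
  sp <- file.path(cfg$out_dir, "summary.txt")
  writeLines(summary_lines, sp)
  res$outputs <- c(res$outputs, sp)
  hs_log("run_full finished")
  invisible(res)
}
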