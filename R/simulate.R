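#' Simulate an unlinked SNP panel under a demographic scenario
#'
#' Each site carries an independent genealogy drawn backward in time under
#' the structured coalescent with the scenario's splits and pulses; one
#' mutation is placed uniformly on the genealogy, so every retained site
#' segregates across the full sample.  Suited to the independence
#' assumptions of the f-statistics and ABC summary statistics.
#'
#' @param scenario a [demographic_scenario()]
#' @param n_sites number of unlinked SNPs
#' @param seed integer seed; identical seeds give identical panels
#' @param spacing_bp synthetic spacing between consecutive site positions
#'   (default 1000 bp on one synthetic scaffold)
#' @return A list with elements `panel` (a [snp_panel()]) and `params`
#'   (the realized generating conditions: scenario, n_sites, seed).
#' @export
simulate_panel <- function(scenario, n_sites, seed, spacing_bp = 1000L) {
  stopifnot(inherits(scenario, "demographic_scenario"), n_sites >= 1)
  validate_scenario(scenario)
  pops <- scenario$populations
  nsam_hap <- as.integer(2L * pops$n_diploid)
  ev <- scenario_events(scenario)
  set.seed(seed)
  H <- .sim_sites_cpp(nsam_hap, pops$ne, ev, as.integer(n_sites))
  # pair consecutive haploid copies into diploid dosages
  odd <- seq(1, ncol(H), by = 2)
  dos <- H[, odd, drop = FALSE] + H[, odd + 1L, drop = FALSE]
  pop_of <- rep(pops$name, pops$n_diploid)
  # sample order follows the haploid layout (population order)
  ids <- paste0(pop_of, "_", stats::ave(seq_along(pop_of), pop_of,
                                        FUN = seq_along))
  colnames(dos) <- ids
  sites <- data.frame(scaffold = "scaffold_1",
                      pos = seq_len(n_sites) * as.integer(spacing_bp),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  panel <- snp_panel(sites, dos, setNames(pop_of, ids))
  list(panel = panel,
       params = list(scenario = scenario, n_sites = n_sites, seed = seed))
}

#' Simulate per-window gene trees under a demographic scenario
#'
#' One genealogy per window (free recombination between windows, none
#' within), windows tiled at `window_bp` width on a synthetic scaffold.
#' Tips are haploid genome copies labelled `<population>_<i>`.
#'
#' @param scenario a [demographic_scenario()]
#' @param n_windows number of windows
#' @param seed integer seed
#' @param window_bp window width in bp (default 50000)
#' @return A `gene_tree_set`: list with `windows` (scaffold, start, end),
#'   `trees` (a `multiPhylo`), and `taxon_map` (tip -> population).
#' @export
simulate_gene_trees <- function(scenario, n_windows, seed,
                                window_bp = 50000L) {
  stopifnot(inherits(scenario, "demographic_scenario"), n_windows >= 1)
  validate_scenario(scenario)
  pops <- scenario$populations
  nsam_hap <- as.integer(2L * pops$n_diploid)
  ev <- scenario_events(scenario)
  set.seed(seed)
  raw <- .sim_trees_cpp(nsam_hap, pops$ne, ev, as.integer(n_windows))
  pop_of <- rep(pops$name, nsam_hap)
  tips <- paste0(pop_of, "_", stats::ave(seq_along(pop_of), pop_of,
                                         FUN = seq_along))
  trees <- lapply(raw, genealogy_to_phylo, tip_labels = tips)
  class(trees) <- "multiPhylo"
  windows <- data.frame(
    scaffold = "scaffold_1",
    start = (seq_len(n_windows) - 1L) * as.integer(window_bp) + 1L,
    end = seq_len(n_windows) * as.integer(window_bp))
  structure(list(windows = windows, trees = trees,
                 taxon_map = setNames(pop_of, tips)),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("<gene_tree_set> ", nrow(x$windows), " windows, ",
      length(x$taxon_map), " tips\n", sep = "")
  invisible(x)
}

# convert the engine's (parent, time) encoding into an ape phylo object
genealogy_to_phylo <- function(g, tip_labels) {
  parent <- g$parent
  ntips <- (length(parent) + 1L) / 2L
  nn <- length(parent)
  # internal nodes were created in coalescent order, root last; ape wants
  # tips 1..n and the root at n+1
  remap <- integer(nn)
  remap[seq_len(ntips)] <- seq_len(ntips)
  remap[(ntips + 1L):nn] <- ntips + 1L + (nn - ((ntips + 1L):nn))
  child <- which(parent >= 0)
  edge <- cbind(remap[parent[child] + 1L], remap[child])
  len <- g$time[parent[child] + 1L] - g$time[child]
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = tip_labels, Nnode = ntips - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate read counts at heterozygous sites
#'
#' Generates per-site (reference, alternate) read counts at sites that are
#' heterozygous in a genome of the given ploidy: a dosage class k is drawn
#' uniformly from 1..(ploidy-1), coverage is Poisson around
#' `mean_coverage`, and the alternate read count is binomial with success
#' probability k/ploidy perturbed by the sequencing error rate (errors
#' flip reads in both directions).
#'
#' @param ploidy integer in 2..8
#' @param n_sites number of heterozygous sites
#' @param mean_coverage mean sequencing depth per site
#' @param error_rate per-read error probability in `[0, 0.5)`
#' @param seed integer seed
#' @return A data.frame of class `site_read_counts` with columns `ref`,
#'   `alt`, `dosage`, and attribute `ploidy`.
#' @export
simulate_read_counts <- function(ploidy, n_sites, mean_coverage,
                                 error_rate = 0.01, seed = 1L) {
  if (ploidy < 2 || ploidy > 8)
    stop("heterozygous sites require ploidy in 2..8")
  stopifnot(mean_coverage > 0, error_rate >= 0, error_rate < 0.5)
  set.seed(seed)
  if (n_sites == 0) {
    out <- data.frame(ref = integer(), alt = integer(), dosage = integer())
  } else {
    k <- sample.int(ploidy - 1L, n_sites, replace = TRUE)
    cov <- rpois(n_sites, mean_coverage)
    p <- k / ploidy
    p_eff <- p * (1 - error_rate) + (1 - p) * error_rate
    alt <- rbinom(n_sites, cov, p_eff)
    out <- data.frame(ref = cov - alt, alt = alt, dosage = k)
  }
  attr(out, "ploidy") <- as.integer(ploidy)
  class(out) <- c("site_read_counts", "data.frame")
  out
}
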