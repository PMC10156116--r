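#' Topology weighting of a single gene tree
#'
#' Quantifies, for one multi-tip gene tree, the weight of each of the
#' three possible rooted topologies relating three ingroup taxa given an
#' outgroup.  The weight of topology T is the fraction of
#' one-tip-per-group subsamples whose induced (unrooted) quartet places
#' the corresponding ingroup pair together against the third ingroup and
#' the outgroup.  All combinations are enumerated exhaustively when the
#' product of group sizes is at most `exhaustive_limit`; otherwise
#' `n_samples` Monte Carlo draws are used.  Subsampled quartets that do
#' not resolve (polytomies) contribute 1/3 to each topology, which keeps
#' the weights normalized without biasing any topology.
#'
#' Topologies are labelled by the sister pair of ingroup labels in sorted
#' order: with ingroups g1 < g2 < g3 the columns are `(g1,g2)`, `(g1,g3)`,
#' `(g2,g3)`.
#'
#' @param tree rooted `phylo` gene tree
#' @param taxon_map named character vector, tip label -> group, covering
#'   three ingroups and one outgroup group
#' @param outgroup name of the outgroup group in `taxon_map`
#' @param exhaustive_limit enumerate exhaustively up to this many
#'   combinations (default 10000)
#' @param n_samples Monte Carlo draws above the limit (default 1000)
#' @return Named numeric vector of 3 weights (sums to 1), with attributes
#'   `method` ("exhaustive" or "monte-carlo") and `n` (combinations used).
#' @export
weight_gene_tree <- function(tree, taxon_map, outgroup,
                             exhaustive_limit = 10000, n_samples = 1000) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; root it on the outgroup first")
  tm <- taxon_map[tree$tip.label]
  if (anyNA(tm)) stop("taxon_map must cover every tip of the tree")
  groups <- sort(setdiff(unique(tm), outgroup))
  if (length(groups) != 3 || !outgroup %in% tm)
    stop("need exactly three ingroup groups plus the outgroup '",
         outgroup, "' among the tips")
  gtips <- lapply(c(groups, outgroup), function(g) which(tm == g))
  sizes <- lengths(gtips)
  if (any(sizes == 0)) stop("every group needs at least one tip")

  # pairwise MRCA of tips and topological node depths, computed once
  mr <- ape::mrca(tree)
  depth <- node_depths(tree)

  n_comb <- prod(sizes)
  if (n_comb <= exhaustive_limit) {
    combos <- as.matrix(expand.grid(gtips[[1]], gtips[[2]], gtips[[3]],
                                    gtips[[4]]))
    method <- "exhaustive"
  } else {
    combos <- cbind(sample(gtips[[1]], n_samples, replace = TRUE),
                    sample(gtips[[2]], n_samples, replace = TRUE),
                    sample(gtips[[3]], n_samples, replace = TRUE),
                    sample(gtips[[4]], n_samples, replace = TRUE))
    method <- "monte-carlo"
  }
  w <- quartet_weights(combos, mr, depth)
  names(w) <- c(paste0("(", groups[1], ",", groups[2], ")"),
                paste0("(", groups[1], ",", groups[3], ")"),
                paste0("(", groups[2], ",", groups[3], ")"))
  attr(w, "method") <- method
  attr(w, "n") <- nrow(combos)
  w
}

# topological depth (edges from root) of every node
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- rep(NA_real_, nn)
  root <- ntip + 1L
  depth[root] <- 0
  # cladewise edge order guarantees parents are visited before children
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(e))) depth[e[i, 2]] <- depth[e[i, 1]] + 1
  depth
}

# vectorized quartet resolution: columns of `combos` are tips (a, b, c, o)
# for ingroups 1..3 and the outgroup.  Returns weights for topologies
# 12|3, 13|2, 23|1.  The deepest pairwise MRCA among the six pairs
# identifies a cherry of the induced quartet; ties that are not between
# complementary pairs mean the quartet is unresolved (polytomy) and
# contribute 1/3 to each topology.
quartet_weights <- function(combos, mr, depth) {
  a <- combos[, 1]; b <- combos[, 2]; cc <- combos[, 3]; o <- combos[, 4]
  d <- cbind(ab = depth[mr[cbind(a, b)]],
             ac = depth[mr[cbind(a, cc)]],
             bc = depth[mr[cbind(b, cc)]],
             ao = depth[mr[cbind(a, o)]],
             bo = depth[mr[cbind(b, o)]],
             co = depth[mr[cbind(cc, o)]])
  dmax <- d[cbind(seq_len(nrow(d)), max.col(d, ties.method = "first"))]
  at_max <- d == dmax
  # complementary pairs: (ab, co) -> topo 1, (ac, bo) -> topo 2,
  # (bc, ao) -> topo 3
  t1 <- (at_max[, "ab"] | at_max[, "co"])
  t2 <- (at_max[, "ac"] | at_max[, "bo"])
  t3 <- (at_max[, "bc"] | at_max[, "ao"])
  resolved <- (t1 + t2 + t3) == 1
  w <- c(sum(t1 & resolved), sum(t2 & resolved), sum(t3 & resolved))
  unres <- sum(!resolved)
  (w + unres / 3) / nrow(d)
}

#' Topology weighting over a set of gene trees
#'
#' Applies [weight_gene_tree()] to every window of a gene tree set and
#' reports per-window weights plus the across-genome mean weight per
#' topology.
#'
#' @param trees a `gene_tree_set` (from [simulate_gene_trees()] or
#'   [read_gene_trees()])
#' @param outgroup name of the outgroup group
#' @param taxon_map optional tip -> group map (defaults to the set's own)
#' @param exhaustive_limit,n_samples passed to [weight_gene_tree()]
#' @return A data.frame of class `topology_weights` with window
#'   coordinates and one weight column per topology; the across-genome
#'   means are in `attr(, "mean_weights")`.
#' @export
weight_set <- function(trees, outgroup, taxon_map = NULL,
                       exhaustive_limit = 10000, n_samples = 1000) {
  stopifnot(inherits(trees, "gene_tree_set"))
  if (is.null(taxon_map)) taxon_map <- trees$taxon_map
  ws <- vector("list", length(trees$trees))
  for (i in seq_along(trees$trees)) {
    ws[[i]] <- tryCatch(
      weight_gene_tree(trees$trees[[i]], taxon_map, outgroup,
                       exhaustive_limit, n_samples),
      error = function(e) stop("window ", i, " (",
                               trees$windows$scaffold[i], ":",
                               trees$windows$start[i], "-",
                               trees$windows$end[i], "): ",
                               conditionMessage(e)))
  }
  W <- do.call(rbind, ws)
  out <- cbind(trees$windows, as.data.frame(W, check.names = FALSE))
  attr(out, "mean_weights") <- colMeans(W)
  attr(out, "topologies") <- colnames(W)
  class(out) <- c("topology_weights", "data.frame")
  out
}

#' Smooth topology weights along scaffolds
#'
#' Rectangular-kernel local mean: for each window midpoint, the smoothed
#' weight of a topology is the mean over windows (same scaffold) whose
#' midpoints fall within half the span on either side, renormalized to
#' sum to one.
#'
#' @param weights a `topology_weights` table
#' @param span_bp smoothing span in bp (default 1e6)
#' @return A data.frame of class `smoothed_weights` with scaffold,
#'   midpoint and smoothed weights.
#' @export
smooth_weights <- function(weights, span_bp = 1e6) {
  stopifnot(inherits(weights, "topology_weights"))
  topo <- attr(weights, "topologies")
  mid <- (weights$start + weights$end) / 2
  if (span_bp < min(weights$end - weights$start + 1)) {
    warning("span smaller than window width: identity smoothing")
    out <- data.frame(scaffold = weights$scaffold, midpoint = mid,
                      weights[, topo, drop = FALSE], check.names = FALSE)
    class(out) <- c("smoothed_weights", "data.frame")
    return(out)
  }
  sm <- matrix(NA_real_, nrow(weights), length(topo),
               dimnames = list(NULL, topo))
  for (sc in unique(weights$scaffold)) {
    idx <- which(weights$scaffold == sc)
    m <- mid[idx]
    for (i in seq_along(idx)) {
      sel <- idx[abs(m - m[i]) <= span_bp / 2]
      v <- colMeans(weights[sel, topo, drop = FALSE])
      sm[idx[i], ] <- v / sum(v)
    }
  }
  out <- data.frame(scaffold = weights$scaffold, midpoint = mid, sm,
                    check.names = FALSE)
  class(out) <- c("smoothed_weights", "data.frame")
  out
}

#' Read gene trees from a Newick file with a window sidecar
#'
#' @param newick_path one Newick tree per line
#' @param windows_path BED-like TSV: scaffold, start, end (1-based
#'   inclusive), one row per tree
#' @param taxon_map_path two-column whitespace-separated file (tip, group)
#' @return A `gene_tree_set`.
#' @export
read_gene_trees <- function(newick_path, windows_path, taxon_map_path) {
  trees <- ape::read.tree(newick_path)
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    class(trees) <- "multiPhylo"
  }
  win <- read.table(windows_path, header = FALSE,
                    col.names = c("scaffold", "start", "end"))
  if (nrow(win) != length(trees))
    stop("window sidecar rows (", nrow(win), ") != trees (",
         length(trees), ")")
  tm <- read_popmap(taxon_map_path)
  structure(list(windows = win, trees = trees, taxon_map = tm),
            class = "gene_tree_set")
}

#' Write a gene tree set as Newick + window sidecar
#' @param trees a `gene_tree_set`
#' @param newick_path,windows_path,taxon_map_path output paths
#' @return `newick_path`, invisibly
#' @export
write_gene_trees <- function(trees, newick_path, windows_path,
                             taxon_map_path) {
  ape::write.tree(trees$trees, file = newick_path)
  write.table(trees$windows, windows_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(trees$taxon_map), unname(trees$taxon_map)),
              taxon_map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(newick_path)
}
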