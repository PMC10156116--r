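#' Block-jackknife summary of per-block statistics
#'
#' Given per-block values of a statistic (e.g. per-block means of an
#' f-statistic numerator) and block weights (e.g. SNP counts), computes
#' the weighted overall estimate, the weighted delete-one-block jackknife
#' standard error, and the z-score `estimate / SE`.  Significance is
#' conventionally assessed at `|z| > 3`.
#'
#' @param block_values numeric vector of per-block statistic values
#' @param block_weights positive weights, one per block (default equal)
#' @return A `jackknife_stat`: list with `estimate`, `se`, `z`,
#'   `n_blocks`, `block_size`.  When all blocks are identical the SE is 0
#'   and `z` is reported as `NA` (undefined), not infinite.
#' @export
block_jackknife <- function(block_values, block_weights = NULL) {
  n <- length(block_values)
  if (n < 2) stop("need at least 2 blocks for a jackknife SE")
  if (is.null(block_weights)) block_weights <- rep(1, n)
  if (length(block_weights) != n || any(block_weights <= 0))
    stop("block_weights must be positive, one per block")
  W <- sum(block_weights)
  est <- sum(block_weights * block_values) / W
  loo <- (est * W - block_weights * block_values) / (W - block_weights)
  jackknife_from_loo(est, loo, block_weights)
}

# weighted delete-one jackknife (Busing et al. 1999, as used by the
# AdmixTools family): est is the full estimate, loo the leave-one-out
# estimates, weights the block weights
jackknife_from_loo <- function(est, loo, weights, block_size = NA_integer_) {
  n <- length(loo)
  W <- sum(weights)
  h <- W / weights
  est_j <- n * est - sum((1 - weights / W) * loo)
  pseudo <- h * est - (h - 1) * loo
  v <- sum((pseudo - est_j)^2 / (h - 1)) / n
  se <- sqrt(max(v, 0))
  z <- if (se > 0) est / se else NA_real_
  structure(list(estimate = est, se = se, z = z, n_blocks = n,
                 block_size = block_size),
            class = "jackknife_stat")
}

#' @export
print.jackknife_stat <- function(x, ...) {
  cat(sprintf("estimate %.6g  SE %.3g  z %s  (%d blocks)\n",
              x$estimate, x$se,
              if (is.na(x$z)) "undefined" else sprintf("%.2f", x$z),
              x$n_blocks))
  invisible(x)
}

# shared plumbing: per-site products -> per-block means -> jackknife.
# Sites with any NA among the populations involved are excluded.
mean_stat_jackknife <- function(values, blocks) {
  ok <- !is.na(values)
  if (!any(ok)) stop("no informative sites")
  if (is.null(blocks)) {
    return(structure(list(estimate = mean(values[ok]), se = NA_real_,
                          z = NA_real_, n_blocks = 1L,
                          block_size = NA_integer_),
                     class = "jackknife_stat"))
  }
  bv <- bw <- numeric(0)
  for (j in seq_len(blocks$n_blocks)) {
    idx <- blocks$starts[j]:blocks$ends[j]
    v <- values[idx]
    v <- v[!is.na(v)]
    if (length(v) > 0) {
      bv <- c(bv, mean(v))
      bw <- c(bw, length(v))
    }
  }
  if (length(bv) < 2) stop("need at least 2 non-empty blocks")
  out <- block_jackknife(bv, bw)
  out$block_size <- blocks$block_size
  out
}

# ratio statistics (D, f4-ratio): delete one block jointly from numerator
# and denominator sums
ratio_stat_jackknife <- function(num, den, blocks, zero_msg) {
  ok <- !is.na(num) & !is.na(den)
  if (!any(ok)) stop("no informative sites")
  Sn <- sum(num[ok]); Sd <- sum(den[ok])
  if (abs(Sd) < 1e-12) stop(zero_msg)
  est <- Sn / Sd
  if (is.null(blocks)) {
    return(structure(list(estimate = est, se = NA_real_, z = NA_real_,
                          n_blocks = 1L, block_size = NA_integer_),
                     class = "jackknife_stat"))
  }
  loo <- w <- numeric(0)
  for (j in seq_len(blocks$n_blocks)) {
    idx <- blocks$starts[j]:blocks$ends[j]
    oj <- ok[idx]
    nj <- sum(oj)
    if (nj > 0) {
      dj <- Sd - sum(den[idx][oj])
      loo <- c(loo, if (abs(dj) < 1e-12) NA_real_
               else (Sn - sum(num[idx][oj])) / dj)
      w <- c(w, nj)
    }
  }
  keep <- !is.na(loo)
  if (sum(keep) < 2) stop("need at least 2 non-empty blocks")
  out <- jackknife_from_loo(est, loo[keep], w[keep],
                            block_size = blocks$block_size)
  out
}

check_pops <- function(freqs, pops) {
  miss <- setdiff(pops, colnames(freqs$freq))
  if (length(miss) > 0)
    stop("population(s) absent from frequency table: ",
         paste(miss, collapse = ", "))
}

#' Construct a frequency table from matrices
#'
#' Mostly useful for worked examples and tests; analyses normally obtain
#' tables from [compute_freqs()] or [polarize_by_outgroup()].
#'
#' @param freq sites x populations matrix of allele frequencies with
#'   population column names
#' @param count matching matrix of allele counts used per cell; `Inf`
#'   (the default) means frequencies are exact, which disables
#'   small-sample corrections
#' @param sites optional coordinate data.frame (`scaffold`, `pos`)
#' @param polarized whether frequencies are derived-allele frequencies
#' @return A `freq_table`.
#' @export
freq_table <- function(freq, count = NULL, sites = NULL,
                       polarized = FALSE) {
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) stop("freq needs population column names")
  if (is.null(count))
    count <- matrix(Inf, nrow(freq), ncol(freq),
                    dimnames = dimnames(freq))
  if (is.null(sites))
    sites <- data.frame(scaffold = "scaffold_1", pos = seq_len(nrow(freq)))
  new_freq_table(sites, freq, count, polarized, derived_is_alt = NULL)
}

# unbiased estimate of the sampling variance of an allele frequency
# estimated from n alleles: p(1-p)/(n-1); 0 when counts are Inf
sampling_var <- function(freqs, P) {
  p <- freqs$freq[, P]
  n <- freqs$count[, P]
  ifelse(is.finite(n) & n > 1, p * (1 - p) / (n - 1), 0)
}

# per-site f4 products (a-b)(c-d), optionally with the unbiased
# small-sample correction: populations shared between the two factors
# contribute sampling-covariance terms
# Cov(a,c) - Cov(a,d) - Cov(b,c) + Cov(b,d) that are removed using
# p(1-p)/(n-1) as the variance estimate
site_f4 <- function(freqs, A, B, C, D, corrected = FALSE) {
  v <- (freqs$freq[, A] - freqs$freq[, B]) *
    (freqs$freq[, C] - freqs$freq[, D])
  if (corrected) {
    adj <- 0
    if (A == C) adj <- adj + sampling_var(freqs, A)
    if (A == D) adj <- adj - sampling_var(freqs, A)
    if (B == C) adj <- adj - sampling_var(freqs, B)
    if (B == D) adj <- adj + sampling_var(freqs, B)
    v <- v - adj
  }
  v
}

#' f3 admixture statistic
#'
#' `f3(C; A, B) = E[(c - a)(c - b)]` over sites.  A significantly negative
#' value (z < -3) indicates that allele frequencies of `C` are intermediate
#' between `A` and `B` at many sites, consistent with `C` being admixed
#' between them; positive values are uninformative.  The uncorrected
#' frequency-product estimator is used (no small-sample heterozygosity
#' correction), matching TreeMix's threepop.
#'
#' @param freqs a `freq_table`
#' @param A,B reference populations
#' @param C test (putative hybrid) population
#' @param blocks a `block_index` from [partition_blocks()], or `NULL` for
#'   a point estimate without SE
#' @param corrected subtract the unbiased estimate `c(1-c)/(n-1)` of the
#'   sampling variance of the test population's frequency (default
#'   `FALSE`, the plain frequency product).  The correction matters for
#'   small per-population sample sizes, where the sampling variance
#'   otherwise biases f3 upward and can mask admixture.
#' @return A `jackknife_stat`.
#' @export
f3 <- function(freqs, A, B, C, blocks = NULL, corrected = FALSE) {
  check_pops(freqs, c(A, B, C))
  mean_stat_jackknife(site_f4(freqs, C, A, C, B, corrected), blocks)
}

#' f4 statistic of treeness
#'
#' `f4(A, B; C, D) = E[(a - b)(c - d)]`.  Under a bifurcating history with
#' `(A,B)` on one side and `(C,D)` on the other, the frequency contrasts
#' are uncorrelated and f4 = 0; significant deviations (|z| > 3) indicate
#' gene flow linking the two sides.
#'
#' @param freqs a `freq_table`
#' @param A,B first population pair
#' @param C,D second population pair
#' @param blocks a `block_index`, or `NULL` for a point estimate
#' @param corrected remove sampling-covariance bias terms for populations
#'   shared between the two pairs (no effect when all four populations
#'   are distinct; default `FALSE`)
#' @return A `jackknife_stat`.
#' @export
f4 <- function(freqs, A, B, C, D, blocks = NULL, corrected = FALSE) {
  if (A == B || C == D) stop("population pairs must be distinct")
  check_pops(freqs, c(A, B, C, D))
  mean_stat_jackknife(site_f4(freqs, A, B, C, D, corrected), blocks)
}

#' D statistic (ABBA-BABA)
#'
#' For the asymmetric four-taxon setup \{\[(P1, P2), P3\], O\}, computes
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` with site pattern
#' probabilities from derived-allele frequencies:
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`.
#' Gene flow between P2 and P3 yields an ABBA excess (D > 0), between P1
#' and P3 a BABA excess (D < 0).  Requires a table polarized with
#' [polarize_by_outgroup()] so that the outgroup frequency defines the
#' ancestral state.
#'
#' @param freqs a polarized `freq_table`
#' @param P1,P2 sister ingroup pair
#' @param P3 candidate donor lineage
#' @param O outgroup used for polarization
#' @param blocks a `block_index`, or `NULL` for a point estimate
#' @return A `jackknife_stat`.
#' @export
d_stat <- function(freqs, P1, P2, P3, O, blocks = NULL) {
  if (!isTRUE(freqs$polarized))
    stop("d_stat requires a table polarized by the outgroup; ",
         "use polarize_by_outgroup()")
  check_pops(freqs, c(P1, P2, P3, O))
  p1 <- freqs$freq[, P1]; p2 <- freqs$freq[, P2]
  p3 <- freqs$freq[, P3]; pO <- freqs$freq[, O]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  ratio_stat_jackknife(abba - baba, abba + baba, blocks,
                       zero_msg = "no informative sites")
}

#' f4-ratio ancestry proportion
#'
#' Estimates the `B`-ancestry proportion of a candidate hybrid `X` between
#' sources `B` and `C` as the quotient
#' `f4(A, O; X, C) / f4(A, O; B, C)`, where `A` is a sister lineage of
#' `B` not involved in the admixture and `O` an outgroup.  When sitewise
#' `x = g b + (1 - g) c`, the ratio equals `g` exactly.  The jackknife
#' deletes each block jointly from numerator and denominator.
#'
#' @param freqs a `freq_table`
#' @param A sister lineage of `B`
#' @param O outgroup
#' @param X candidate hybrid
#' @param B,C the two source populations
#' @param blocks a `block_index`, or `NULL` for a point estimate
#' @param corrected remove sampling-covariance bias terms for repeated
#'   populations (default `TRUE`; no effect when all five populations
#'   are distinct)
#' @return A `jackknife_stat` whose estimate is the ancestry proportion.
#' @export
f4_ratio <- function(freqs, A, O, X, B, C, blocks = NULL,
                     corrected = TRUE) {
  check_pops(freqs, c(A, O, X, B, C))
  ratio_stat_jackknife(site_f4(freqs, A, O, X, C, corrected),
                       site_f4(freqs, A, O, B, C, corrected), blocks,
                       zero_msg = "uninformative configuration: denominator f4 is 0")
}

# Green-style admixture fraction of X from donor C, using A as X's sister:
# f4(A, X; C, O) / f4(A, C; C, O).  Used by f_branch.  Always corrected
# for the repeated C in the denominator.
f_g <- function(freqs, A, X, C, O, blocks = NULL) {
  check_pops(freqs, c(A, X, C, O))
  ratio_stat_jackknife(site_f4(freqs, A, X, C, O, corrected = TRUE),
                       site_f4(freqs, A, C, C, O, corrected = TRUE), blocks,
                       zero_msg = "uninformative configuration: denominator f4 is 0")
}

#' Hudson's FST between two populations
#'
#' Ratio-of-averages Hudson estimator with sample-size correction
#' (Bhatia et al. 2013): per-site numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` over denominator
#' `p1(1-p2) + p2(1-p1)`, with `n` the allele counts.
#'
#' @param freqs a `freq_table`
#' @param P1,P2 population labels
#' @param blocks a `block_index`, or `NULL` for a point estimate
#' @return A `jackknife_stat`.
#' @export
hudson_fst <- function(freqs, P1, P2, blocks = NULL) {
  check_pops(freqs, c(P1, P2))
  p1 <- freqs$freq[, P1]; p2 <- freqs$freq[, P2]
  n1 <- freqs$count[, P1]; n2 <- freqs$count[, P2]
  ok <- n1 > 1 & n2 > 1
  num <- ifelse(ok, (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                  p2 * (1 - p2) / (n2 - 1), NA_real_)
  den <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), NA_real_)
  ratio_stat_jackknife(num, den, blocks, zero_msg = "no informative sites")
}

#' f-branch matrix of excess allele sharing
#'
#' Assigns f4-ratio-based excess-allele-sharing signals to branches of a
#' rooted population tree.  For every branch `b` (terminal or internal,
#' excluding the root) and every population `C` that descends from neither
#' `b` nor its sister, the cell is the minimum over descendants `X` of `b`
#' and sisters `A` of the Green-style admixture fraction
#' `f4(A, X; C, O) / f4(A, C; C, O)` (minimum chosen for conservatism, as
#' in tree-aware f4-ratio summaries).  Cells whose configuration is
#' undefined are marked inestimable.  Significance: jackknife z > 3 for
#' the minimizing configuration.
#'
#' @param tree rooted `phylo` whose tip labels are population names; may
#'   include the outgroup as a tip (it is removed before branch
#'   enumeration).
#' @param freqs a `freq_table` containing all tree tips and the outgroup
#' @param O outgroup population label
#' @param blocks a `block_index`
#' @return An `f_branch` object: matrices `estimate`, `z`, logicals
#'   `significant` and `estimable` (branches x populations).
#' @export
f_branch <- function(tree, freqs, O, blocks) {
  stopifnot(inherits(tree, "phylo"))
  if (O %in% tree$tip.label)
    tree <- ape::drop.tip(tree, O)
  tips <- tree$tip.label
  if (length(tips) < 3 || !(O %in% colnames(freqs$freq)))
    stop("need an ingroup tree with >= 3 tips plus the outgroup ",
         "(>= 4 populations in total)")
  check_pops(freqs, c(tips, O))
  ntip <- length(tips)
  nodes <- setdiff(seq_len(ntip + tree$Nnode), ntip + 1L)  # all but root
  desc <- lapply(nodes, function(nd) {
    if (nd <= ntip) tips[nd]
    else tips[intersect(phangorn_free_descendants(tree, nd), seq_len(ntip))]
  })
  parent <- tree$edge[match(nodes, tree$edge[, 2]), 1]
  branch_label <- vapply(seq_along(nodes), function(i) {
    d <- desc[[i]]
    if (length(d) == 1) d else paste0("anc(", paste(d, collapse = ","), ")")
  }, character(1))
  est <- zz <- matrix(NA_real_, length(nodes), ntip,
                      dimnames = list(branch_label, tips))
  estimable <- matrix(FALSE, length(nodes), ntip,
                      dimnames = list(branch_label, tips))
  for (i in seq_along(nodes)) {
    sib_desc <- setdiff(desc_of_node(tree, parent[i]), desc[[i]])
    for (C in tips) {
      if (C %in% desc[[i]] || !length(setdiff(sib_desc, C)) ||
          !length(setdiff(desc[[i]], C)) || C %in% sib_desc)
        next
      best <- NULL
      for (X in desc[[i]]) for (A in sib_desc) {
        r <- tryCatch(f_g(freqs, A, X, C, O, blocks), error = function(e) NULL)
        if (!is.null(r) && (is.null(best) || r$estimate < best$estimate))
          best <- r
      }
      if (!is.null(best)) {
        estimable[i, C] <- TRUE
        est[i, C] <- best$estimate
        zz[i, C] <- best$z
      }
    }
  }
  structure(list(estimate = est, z = zz,
                 significant = !is.na(zz) & zz > 3,
                 estimable = estimable, outgroup = O),
            class = "f_branch")
}

# tip-and-node descendants of an internal node (indices)
desc_of_node <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  ids <- phangorn_free_descendants(tree, nd)
  tree$tip.label[ids[ids <= ntip]]
}

# descendants by edge traversal (avoids a phangorn dependency)
phangorn_free_descendants <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  if (nd <= ntip) return(nd)
  out <- integer(0)
  stack <- nd
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' @export
print.f_branch <- function(x, ...) {
  cat("<f_branch> ", nrow(x$estimate), " branches x ", ncol(x$estimate),
      " populations; ", sum(x$significant, na.rm = TRUE),
      " significant cell(s) (z > 3)\n", sep = "")
  invisible(x)
}

#' Ancestry proportion of a hybrid from a taxon triple plus outgroup
#'
#' Estimates the `P2`-ancestry proportion of a candidate hybrid from the
#' four populations (P1, hybrid, P2, outgroup) alone.  A single f4-ratio
#' is biased here because one parent must be reused across the two f4
#' factors: the P1-reuse form `f4(P1,O;X,P1)/f4(P1,O;P2,P1)` is inflated
#' by P1's post-admixture drift, while the Green form
#' `f4(P1,X;P2,O)/f4(P1,P2;P2,O)` is attenuated by P2's.  Writing both as
#' functions of the shared drift terms and solving gives the combination
#' `gamma = g2 / (1 - g1 + g2)`, which cancels the drift terms exactly
#' when the parents' post-admixture drifts are symmetric and reduces to
#' the plain ratio on drift-free algebraic mixtures.  Small-sample
#' corrections are applied to every f4 product.
#'
#' @param freqs a `freq_table`
#' @param P1,P2 the two parental candidates
#' @param X the candidate hybrid
#' @param O outgroup population label
#' @param blocks a `block_index`, or `NULL` for a point estimate
#' @return A `jackknife_stat` whose estimate is the P2-ancestry of `X`.
#' @export
triple_gamma <- function(freqs, P1, X, P2, O, blocks = NULL) {
  check_pops(freqs, c(P1, X, P2, O))
  n1 <- site_f4(freqs, P1, O, X, P1, corrected = TRUE)
  d1 <- site_f4(freqs, P1, O, P2, P1, corrected = TRUE)
  n2 <- site_f4(freqs, P1, X, P2, O, corrected = TRUE)
  d2 <- site_f4(freqs, P1, P2, P2, O, corrected = TRUE)
  ok <- !(is.na(n1) | is.na(d1) | is.na(n2) | is.na(d2))
  if (!any(ok)) stop("no informative sites")
  gamma_of <- function(s1, s2, s3, s4) {
    g1 <- s1 / s2
    g2 <- s3 / s4
    g2 / (1 - g1 + g2)
  }
  S <- c(sum(n1[ok]), sum(d1[ok]), sum(n2[ok]), sum(d2[ok]))
  est <- gamma_of(S[1], S[2], S[3], S[4])
  if (is.null(blocks))
    return(structure(list(estimate = est, se = NA_real_, z = NA_real_,
                          n_blocks = 1L, block_size = NA_integer_),
                     class = "jackknife_stat"))
  loo <- w <- numeric(0)
  for (j in seq_len(blocks$n_blocks)) {
    bi <- blocks$starts[j]:blocks$ends[j]
    oj <- ok[bi]
    nj <- sum(oj)
    if (nj > 0) {
      loo <- c(loo, gamma_of(S[1] - sum(n1[bi][oj]),
                             S[2] - sum(d1[bi][oj]),
                             S[3] - sum(n2[bi][oj]),
                             S[4] - sum(d2[bi][oj])))
      w <- c(w, nj)
    }
  }
  keep <- is.finite(loo)
  if (sum(keep) < 2) stop("need at least 2 non-empty blocks")
  jackknife_from_loo(est, loo[keep], w[keep],
                     block_size = blocks$block_size)
}

#' Scan taxon triples for hybridization signals
#'
#' For every unordered triple of non-outgroup populations and every
#' candidate hybrid within it, tests `f3(hybrid; P1, P2)` with the
#' small-sample correction; when the f3 z-score is below -3 (significant
#' admixture signal) the `P2`-ancestry proportion `gamma` of the hybrid
#' is estimated with [triple_gamma()].
#'
#' @param freqs a `freq_table`
#' @param O outgroup population label
#' @param blocks a `block_index`
#' @return A data.frame of class `triple_test_table` with one row per
#'   (P1, hybrid, P2) assignment: `f3`, `z`, `significant`, `gamma`
#'   (`NA` for non-significant rows).
#' @export
hybrid_triple_scan <- function(freqs, O, blocks) {
  pops <- setdiff(colnames(freqs$freq), O)
  if (length(pops) < 3) stop("need at least 3 non-outgroup populations")
  check_pops(freqs, O)
  rows <- list()
  for (tri in utils::combn(sort(pops), 3, simplify = FALSE)) {
    for (H in tri) {
      ps <- sort(setdiff(tri, H))
      r3 <- f3(freqs, ps[1], ps[2], H, blocks, corrected = TRUE)
      sig <- !is.na(r3$z) && r3$z < -3
      gamma <- NA_real_
      if (sig) {
        rg <- tryCatch(triple_gamma(freqs, P1 = ps[1], X = H, P2 = ps[2],
                                    O = O, blocks),
                       error = function(e) NULL)
        if (!is.null(rg)) gamma <- rg$estimate
      }
      rows[[length(rows) + 1]] <-
        data.frame(P1 = ps[1], hybrid = H, P2 = ps[2],
                   f3 = r3$estimate, z = r3$z, significant = sig,
                   gamma = gamma, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("triple_test_table", "data.frame")
  out
}
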