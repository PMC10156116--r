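# brute-force oracle: prune each tip combination to a quartet with ape and
# read off which ingroup pair is monophyletic after rooting on the outgroup
oracle_weights <- function(tree, taxon_map, outgroup) {
  groups <- sort(setdiff(unique(taxon_map), outgroup))
  tips <- lapply(c(groups, outgroup),
                 function(g) names(taxon_map)[taxon_map == g])
  combos <- expand.grid(tips[[1]], tips[[2]], tips[[3]], tips[[4]],
                        stringsAsFactors = FALSE)
  w <- c(0, 0, 0)
  pairs <- list(1:2, c(1, 3), 2:3)
  for (i in seq_len(nrow(combos))) {
    q <- unlist(combos[i, ])
    sub <- ape::keep.tip(tree, q)
    sub <- ape::root(sub, outgroup = q[4], resolve.root = TRUE)
    hit <- vapply(pairs, function(pr)
      ape::is.monophyletic(sub, q[pr]), logical(1))
    if (sum(hit) == 1) w[hit] <- w[hit] + 1
    else w <- w + 1 / 3
  }
  w / nrow(combos)
}

# random coalescent-style tree with nt tips per group
random_group_tree <- function(nt, seed) {
  set.seed(seed)
  labels <- c(paste0("A_", 1:nt), paste0("B_", 1:nt), paste0("C_", 1:nt),
              paste0("O_", 1:nt))
  tr <- ape::rtree(length(labels), tip.label = sample(labels))
  list(tree = tr,
       map = stats::setNames(sub("_.*", "", labels), labels))
}

test_that("a fully concordant tree gives weight (1, 0, 0)", {
  tr <- ape::read.tree(text = "(((A_1:1,A_2:1):1,(B_1:1,B_2:1):1):1,((C_1:1,C_2:1):1,(O_1:1,O_2:1):1):1);")
  tm <- stats::setNames(sub("_.*", "", tr$tip.label), tr$tip.label)
  w <- weight_gene_tree(tr, tm, outgroup = "O")
  expect_equal(as.numeric(w), c(1, 0, 0))
  expect_equal(attr(w, "method"), "exhaustive")
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("a half-and-half tree matches the brute-force oracle", {
  # A_1 sides with B, A_2 with C: half of all combinations induce each
  txt <- "((((A_1:1,B_1:1):1,B_2:1):1,((A_2:1,C_1:1):1,C_2:1):1):1,O_1:2);"
  tr <- ape::read.tree(text = txt)
  tm <- stats::setNames(sub("_.*", "", tr$tip.label), tr$tip.label)
  w <- weight_gene_tree(tr, tm, outgroup = "O")
  expect_equal(as.numeric(w), oracle_weights(tr, tm, "O"))
  expect_equal(as.numeric(w), c(0.5, 0.5, 0))
})

test_that("weights match the oracle on random trees, also under resampling", {
  for (seed in 1:12) {
    rt <- random_group_tree(2, seed)
    w <- weight_gene_tree(rt$tree, rt$map, outgroup = "O")
    expect_equal(as.numeric(w), oracle_weights(rt$tree, rt$map, "O"),
                 tolerance = 1e-12)
  }
  # Monte Carlo agrees with exhaustive within binomial error
  rt <- random_group_tree(3, 99)
  we <- weight_gene_tree(rt$tree, rt$map, outgroup = "O")
  set.seed(1)
  wm <- weight_gene_tree(rt$tree, rt$map, outgroup = "O",
                         exhaustive_limit = 1, n_samples = 10000)
  expect_equal(attr(wm, "method"), "monte-carlo")
  expect_true(max(abs(we - wm)) <= 0.02 +
                3 * sqrt(max(we * (1 - we)) / 10000))
})

test_that("weights ignore tip-label order and rerooting within the outgroup", {
  rt <- random_group_tree(2, 42)
  w1 <- weight_gene_tree(rt$tree, rt$map, outgroup = "O")
  shuffled <- ape::rotateConstr(rt$tree, sample(rt$tree$tip.label))
  w2 <- weight_gene_tree(shuffled, rt$map, outgroup = "O")
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-12)
  rerooted <- ape::root(rt$tree, outgroup = "O_1", resolve.root = TRUE)
  w3 <- weight_gene_tree(rerooted, rt$map, outgroup = "O")
  expect_equal(as.numeric(w1), as.numeric(w3), tolerance = 1e-12)
})

test_that("polytomies contribute 1/3 to each topology", {
  tr <- ape::read.tree(text = "((A_1:1,B_1:1,C_1:1):1,O_1:1);")
  tm <- stats::setNames(sub("_.*", "", tr$tip.label), tr$tip.label)
  w <- weight_gene_tree(tr, tm, outgroup = "O")
  expect_equal(as.numeric(w), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("deep splits give near-complete concordance, star trees 1/3 shares", {
  sc_deep <- demographic_scenario(
    data.frame(name = c("A", "B", "C", "O"), n_diploid = 2, ne = 1000),
    splits = data.frame(time = c(50000, 100000, 200000),
                        derived = c("B", "C", "O"),
                        ancestral = c("A", "A", "A")))
  gt <- simulate_gene_trees(sc_deep, 1000, seed = 21)
  tw <- weight_set(gt, outgroup = "O")
  mw <- attr(tw, "mean_weights")
  expect_gte(mw[["(A,B)"]], 0.95)
  expect_equal(sum(mw), 1, tolerance = 1e-9)

  sc_star <- demographic_scenario(
    data.frame(name = c("A", "B", "C", "O"), n_diploid = 2, ne = 1000),
    splits = data.frame(time = c(1e-6, 2e-6, 200000),
                        derived = c("B", "C", "O"),
                        ancestral = c("A", "A", "A")))
  gt2 <- simulate_gene_trees(sc_star, 1000, seed = 22)
  mw2 <- attr(weight_set(gt2, outgroup = "O"), "mean_weights")
  se <- sqrt(1 / 3 * 2 / 3 / 1000)
  expect_true(all(abs(mw2 - 1 / 3) < 3 * se + 0.02))
})

test_that("smoothing is a renormalized local mean over the span", {
  win <- data.frame(scaffold = "sc1", start = seq(1, by = 50000,
                                                  length.out = 9),
                    end = seq(50000, by = 50000, length.out = 9))
  W <- matrix(rep(c(1, 0, 0), each = 9), 9, 3,
              dimnames = list(NULL, c("(A,B)", "(A,C)", "(B,C)")))
  W[5, ] <- c(0, 1, 0)   # single discordant window mid-run
  tw <- cbind(win, as.data.frame(W, check.names = FALSE))
  attr(tw, "topologies") <- colnames(W)
  class(tw) <- c("topology_weights", "data.frame")
  sm <- smooth_weights(tw, span_bp = 220000)  # covers 5 windows
  expect_equal(sm[5, "(A,B)"], 4 / 5)
  expect_true(all(abs(rowSums(sm[, 3:5]) - 1) < 1e-9))
  # constant weights are unchanged under any span
  tw2 <- tw; tw2[5, c("(A,B)", "(A,C)")] <- c(1, 0)
  sm2 <- smooth_weights(tw2, span_bp = 220000)
  expect_true(all(sm2[, "(A,B)"] == 1))
  expect_warning(smooth_weights(tw, span_bp = 10), "identity")
})
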