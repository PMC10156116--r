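test_that("f3 and f4 match hand-computed products on tiny tables", {
  ft <- freq_table(cbind(A = 1, B = 0, C = 0.5))
  expect_equal(f3(ft, "A", "B", "C")$estimate, -0.25)  # (0.5-1)(0.5-0)
  ft2 <- random_freq_table(200, c("A", "B", "C", "D"), seed = 3)
  ft2$freq[, "C"] <- ft2$freq[, "A"]
  expect_equal(f3(ft2, "A", "B", "C")$estimate, 0)      # c == a everywhere
  ft3 <- random_freq_table(200, c("A", "B", "C", "D"), seed = 4)
  ft3$freq[, "B"] <- ft3$freq[, "A"]
  expect_equal(f4(ft3, "A", "B", "C", "D")$estimate, 0) # a == b exactly
})

test_that("f4 permutation identities hold to machine precision", {
  ft <- random_freq_table(300, c("A", "B", "C", "D"), seed = 5)
  base <- f4(ft, "A", "B", "C", "D")$estimate
  expect_equal(f4(ft, "B", "A", "C", "D")$estimate, -base, tolerance = 1e-14)
  expect_equal(f4(ft, "A", "B", "D", "C")$estimate, -base, tolerance = 1e-14)
  expect_equal(f4(ft, "C", "D", "A", "B")$estimate, base, tolerance = 1e-14)
})

test_that("the whole-panel mean equals the block-weighted mean of block means", {
  ft <- random_freq_table(1003, c("A", "B", "C", "D"), seed = 6)
  v <- (ft$freq[, "A"] - ft$freq[, "B"]) * (ft$freq[, "C"] - ft$freq[, "D"])
  for (L in c(10, 97, 250)) {
    b <- partition_blocks(length(v), L)
    used <- seq_len(b$n_blocks * L)
    r <- f4(ft, "A", "B", "C", "D", b)
    expect_equal(r$estimate, mean(v[used]), tolerance = 1e-14)
  }
})

test_that("vectorized f-statistics agree with a literal site loop", {
  ft <- random_freq_table(400, c("A", "B", "C", "D"), seed = 7)
  f <- ft$freq
  loop_f3 <- 0
  loop_f4 <- 0
  for (i in seq_len(nrow(f))) {
    loop_f3 <- loop_f3 + (f[i, "C"] - f[i, "A"]) * (f[i, "C"] - f[i, "B"])
    loop_f4 <- loop_f4 + (f[i, "A"] - f[i, "B"]) * (f[i, "C"] - f[i, "D"])
  }
  expect_equal(f3(ft, "A", "B", "C")$estimate, unname(loop_f3) / nrow(f),
               tolerance = 1e-12)
  expect_equal(f4(ft, "A", "B", "C", "D")$estimate,
               unname(loop_f4) / nrow(f), tolerance = 1e-12)
})

test_that("block jackknife handles degenerate and calibrated cases", {
  r <- block_jackknife(c(1, -1))
  expect_equal(r$estimate, 0)
  expect_equal(r$z, 0)
  expect_error(block_jackknife(3), "at least 2 blocks")
  same <- block_jackknife(rep(2.5, 10))
  expect_equal(same$se, 0)
  expect_true(is.na(same$z))   # undefined, not infinite
  # classical property: SE of a mean of 500 iid N(0,1) blocks ~ 1/sqrt(500)
  set.seed(8)
  ses <- replicate(100, block_jackknife(rnorm(500))$se)
  expect_lt(abs(mean(ses) - 1 / sqrt(500)) / (1 / sqrt(500)), 0.2)
})

test_that("D statistic matches pattern algebra and detects simulated gene flow", {
  ftp <- freq_table(cbind(P1 = 0, P2 = 1, P3 = 1, O = 0), polarized = TRUE)
  expect_equal(d_stat(ftp, "P1", "P2", "P3", "O")$estimate, 1)
  ft2 <- random_freq_table(200, c("P1", "P2", "P3", "O"), seed = 9)
  ft2$polarized <- TRUE
  ft2$freq[, "P2"] <- ft2$freq[, "P1"]
  expect_equal(d_stat(ft2, "P1", "P2", "P3", "O")$estimate, 0)
  expect_error(d_stat(random_freq_table(5, c("P1", "P2", "P3", "O")),
                      "P1", "P2", "P3", "O"), "polarized")
  # simulation with a P3 -> P2 pulse gives D > 0 with z > 3
  sc <- demographic_scenario(
    populations = data.frame(name = c("P1", "P2", "P3", "O"),
                             n_diploid = 2, ne = 10000),
    splits = data.frame(time = c(10000, 40000, 120000),
                        derived = c("P2", "P3", "O"),
                        ancestral = c("P1", "P1", "P1")),
    pulses = data.frame(time = 2000, recipient = "P2", donor = "P3",
                        alpha = 0.2))
  sim <- simulate_panel(sc, 50000, seed = 10)
  ftp3 <- suppressMessages(polarize_by_outgroup(sim$panel, "O"))
  r <- d_stat(ftp3, "P1", "P2", "P3", "O",
              partition_blocks(nrow(ftp3$freq), 500))
  expect_gt(r$estimate, 0)
  expect_gt(r$z, 3)
})

test_that("f4-ratio recovers algebraic mixture proportions exactly", {
  set.seed(11)
  n <- 300
  b <- runif(n); cc <- runif(n)
  ft <- freq_table(cbind(A = 1, O = 0, X = 0.7 * b + 0.3 * cc,
                         B = b, C = cc))
  expect_equal(f4_ratio(ft, "A", "O", "X", "B", "C")$estimate, 0.7,
               tolerance = 1e-12)
  ft$freq[, "X"] <- b
  expect_equal(f4_ratio(ft, "A", "O", "X", "B", "C")$estimate, 1,
               tolerance = 1e-12)
  # degenerate configuration errors out
  ft$freq[, "B"] <- cc
  expect_error(f4_ratio(ft, "A", "O", "X", "B", "C"), "uninformative")
  # triple_gamma reduces to the plain ratio on drift-free mixtures
  ft2 <- freq_table(cbind(P1 = b, X = 0.6 * b + 0.4 * cc, P2 = cc,
                          O = 0.5))
  expect_equal(triple_gamma(ft2, "P1", "X", "P2", "O")$estimate, 0.4,
               tolerance = 1e-10)
})

test_that("f4-ratio recovers simulated ancestry proportions within 0.1", {
  for (g in c(0.3, 0.5, 0.67)) {
    sc <- fur_seal_history(alpha_gfs = g)
    sim <- simulate_panel(sc, 50000, seed = round(1000 * g))
    ft <- compute_freqs(sim$panel)
    blocks <- partition_blocks(nrow(ft$freq), 1000)
    r <- f4_ratio(ft, A = "SAfs_FK", O = "Afs", X = "Pfs",
                  B = "Gfs", C = "SAfs_AR", blocks)
    expect_lt(abs(r$estimate - g), 0.1)
  }
})

test_that("f3 with the small-sample correction flags the simulated hybrid", {
  sim <- simulate_panel(fur_seal_history(), 100000, seed = 7)
  ft <- compute_freqs(sim$panel)
  blocks <- partition_blocks(nrow(ft$freq), 10000)
  r <- f3(ft, "Gfs", "SAfs_AR", "Pfs", blocks, corrected = TRUE)
  expect_lt(r$estimate, 0)
  expect_lt(r$z, -3)
  # an unadmixed population shows no negative-f3 signal
  r2 <- f3(ft, "Gfs", "Pfs", "SAfs_AR", blocks, corrected = TRUE)
  expect_gt(r2$z, -3)
})
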