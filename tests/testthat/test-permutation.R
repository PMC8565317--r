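# Composition-aware Monte-Carlo null models.

test_that("bin weights are depth shares", {
  w <- compute_bin_weights(rep(5, 10))
  expect_equal(w$weights, rep(0.1, 10))

  w2 <- compute_bin_weights(c(100, 300))
  expect_equal(w2$weights, c(0.25, 0.75))

  w3 <- compute_bin_weights(c(0, 100, 300))
  expect_equal(w3$weights[1], 0)
  expect_equal(sum(w3$weights), 1, tolerance = 1e-12)

  expect_error(compute_bin_weights(rep(0, 5)), "zero total depth")
  expect_error(compute_bin_weights(c(-1, 2)), "non-negative")
})

test_that("permutation p-values hit their boundary cases", {
  S <- rep(1000, 10)
  w <- compute_bin_weights(S, 1:10)
  # an observed slope beyond anything the null can produce
  p0 <- gradient_permutation_test(50, w, S, 1:10, observed_slope = 1,
                                  n_perm = 500, seed = 1)
  expect_equal(p0$p_value, 0)
  expect_equal(p0$count_ge, 0L)
  expect_match(format_perm_p(p0), "^< 0.002")

  # degenerate null: all mass in one bin makes every replicate identical,
  # so a matching observed slope has p = 1 (the >= comparison)
  Sd <- rep(500, 10)
  wd <- compute_bin_weights(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0), 1:10)
  one <- gradient_permutation_test(20, wd, Sd, 1:10, observed_slope = 0,
                                   n_perm = 1, seed = 2)
  pd <- gradient_permutation_test(20, wd, Sd, 1:10,
                                  observed_slope = one$slopes[1],
                                  n_perm = 300, seed = 3)
  expect_equal(pd$p_value, 1)

  expect_error(gradient_permutation_test(50, w, S, 1:10, 0, n_perm = 0),
               "n_perm")
  expect_error(gradient_permutation_test(0, w, S, 1:10, 0, n_perm = 10),
               "mutation")
})

test_that("permutation replicates conserve counts and match their weights", {
  S <- c(200, 800, 400, 600, 1000)
  w <- compute_bin_weights(S, 1:5)
  n <- 120
  r <- gradient_permutation_test(n, w, S, 1:5, observed_slope = 0,
                                 n_perm = 4000, seed = 10,
                                 keep_counts = TRUE)
  expect_true(all(colSums(r$counts) == n))
  # empirical mean per bin within 3 binomial SD of n * w_i
  mu <- rowMeans(r$counts)
  se <- sqrt(n * w$weights * (1 - w$weights) / 4000)
  expect_true(all(abs(mu - n * w$weights) <= 3 * se + 1e-9))
})

test_that("identical seeds reproduce permutation results bit for bit", {
  S <- rpois(30, 700) + 1
  w <- compute_bin_weights(S, 1:30)
  a <- gradient_permutation_test(80, w, S, 5:30, 1e-8, n_perm = 400,
                                 seed = 77)
  b <- gradient_permutation_test(80, w, S, 5:30, 1e-8, n_perm = 400,
                                 seed = 77)
  expect_identical(a$slopes, b$slopes)
  expect_identical(a$p_value, b$p_value)

  s1 <- mcr_hotspot_scan(rpois(20, 5) + 1, rep(1e5, 20), n_perm = 2000,
                         seed = 78)
  s2 <- mcr_hotspot_scan(s1$observed_count, rep(1e5, 20), n_perm = 2000,
                         seed = 78)
  expect_identical(s1$lower, s2$lower)
  expect_identical(s1$upper, s2$upper)
})

test_that("the 20-bin envelope uses the Bonferroni arithmetic", {
  scan <- mcr_hotspot_scan(rep(3, 20), rep(5e4, 20), n_perm = 2000,
                           seed = 5)
  expect_equal(attr(scan, "per_bin_alpha"), 0.0025)
  expect_equal(attr(scan, "envelope_level"), 0.9975)
  expect_equal(100 * attr(scan, "envelope_level"), 99.75)
  # envelope sanity and classification consistency
  expect_true(all(scan$lower <= scan$sim_mean + 1e-12))
  expect_true(all(scan$sim_mean <= scan$upper + 1e-12))
  over <- scan$observed_freq > scan$upper
  under <- scan$observed_freq < scan$lower
  expect_equal(scan$classification == "over", over)
  expect_equal(scan$classification == "under", under)

  expect_error(mcr_hotspot_scan(rep(0, 20), rep(1e4, 20)), "insufficient")
  expect_error(mcr_hotspot_scan(numeric(0), numeric(0)), "insufficient")
})

test_that("tightening the family level never narrows the envelope", {
  counts <- rpois(20, 8) + 1
  S <- rep(2e5, 20)
  tight <- mcr_hotspot_scan(counts, S, n_perm = 5000, family_alpha = 0.01,
                            seed = 6)
  loose <- mcr_hotspot_scan(counts, S, n_perm = 5000, family_alpha = 0.2,
                            seed = 6)
  expect_true(all(tight$lower <= loose$lower + 1e-15))
  expect_true(all(tight$upper >= loose$upper - 1e-15))
})

test_that("a planted cold-spot is flagged under", {
  hits <- 0L
  for (s in 1:40) {
    folds <- rep(1, 20); folds[7] <- 0
    win <- simulate_hotspot_window(20, 1e-4, folds, bin_depth = 2e5,
                                   seed = 400 + s)
    scan <- mcr_hotspot_scan(win$counts, win$bin_depths, n_perm = 20000,
                             seed = 700 + s)
    if (scan$classification[7] == "under") hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})
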