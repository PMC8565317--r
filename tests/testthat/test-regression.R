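# Robust gradient regression: clean-limit equivalence, outlier resistance,
# the vectorized IRLS engine, and the age interaction model.

freq_table <- function(bin, frequency) data.frame(bin = bin,
                                                  frequency = frequency)

test_that("noiseless linear data is fit exactly and matches OLS", {
  x <- 1:50
  tab <- freq_table(x, 2e-6 + 7e-8 * x)
  fh <- fit_arc_gradient(tab, x, estimator = "huber")
  fo <- fit_arc_gradient(tab, x, estimator = "ols")
  expect_equal(fh$slope, 7e-8, tolerance = 1e-12)
  expect_lt(abs(fh$slope - fo$slope), 1e-12 * abs(fo$slope) + 1e-25)
  expect_equal(fh$intercept, 2e-6, tolerance = 1e-10)
})

test_that("constant response gives zero slope with p near 1", {
  tab <- freq_table(1:20, rep(3e-6, 20))
  f <- fit_arc_gradient(tab, 1:20)
  expect_equal(f$slope, 0)
  expect_equal(f$p_value, 1)
})

test_that("fewer than 3 usable bins is an error", {
  tab <- freq_table(1:5, c(1, 2, NA, NA, NA))
  expect_error(fit_arc_gradient(tab, 1:5), "insufficient")
})

test_that("one corrupted bin barely moves the robust slope", {
  set.seed(7)
  x <- 1:100
  y <- 5e-6 + 5e-8 * x + rnorm(100, 0, 3e-7)
  base_h <- fit_arc_gradient(freq_table(x, y), x, estimator = "huber")
  base_o <- fit_arc_gradient(freq_table(x, y), x, estimator = "ols")
  y2 <- y
  y2[90] <- y2[90] * 100
  cor_h <- fit_arc_gradient(freq_table(x, y2), x, estimator = "huber")
  cor_o <- fit_arc_gradient(freq_table(x, y2), x, estimator = "ols")
  expect_lt(abs(cor_h$slope - base_h$slope),
            0.1 * abs(cor_o$slope - base_o$slope))
})

test_that("translation changes only the intercept", {
  set.seed(8)
  x <- 1:40
  y <- 1e-6 + 2e-8 * x + rnorm(40, 0, 1e-7)
  f1 <- fit_arc_gradient(freq_table(x, y), x)
  f2 <- fit_arc_gradient(freq_table(x, y + 5e-6), x)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f2$intercept - f1$intercept, 5e-6, tolerance = 1e-8)
})

test_that("the vectorized IRLS agrees with MASS::rlm", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(20:120, 1)
    x <- seq_len(n)
    y <- 1e-6 + 5e-8 * x + rnorm(n, 0, 2e-7)
    if (i %% 2 == 0) y[sample(n, 3)] <- y[sample(n, 3)] * 25
    ref <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                     scale.est = "MAD", maxit = 400, acc = 1e-10)
    got <- huber_slope_matrix(x, matrix(y, ncol = 1))
    expect_equal(got$slope, unname(coef(ref)[2]),
                 tolerance = 1e-6)
    expect_equal(got$intercept, unname(coef(ref)[1]),
                 tolerance = 1e-5)
  }
  # and with the reported fit, which uses MASS::rlm directly
  set.seed(43)
  x <- 1:60
  y <- 2e-6 + 3e-8 * x + rnorm(60, 0, 1.5e-7)
  y[10] <- y[10] * 30
  f <- fit_arc_gradient(freq_table(x, y), x)
  m <- huber_slope_matrix(x, matrix(y, ncol = 1))
  expect_equal(f$slope, m$slope, tolerance = 1e-6)
})

test_that("slope recovery on a single simulated arc is well calibrated", {
  sim <- simulate_mutation_dataset(quick_config(slope = 8e-8), seed = 99)
  tab <- binned_frequency(sim$records, sim$depths, sim$genome, sim$bins,
                          classes = "G>A")
  f <- fit_arc_gradient(tab, arc_bin_range(mouse_mt_arcs(), "major"),
                        class = "G>A", arc = "major")
  expect_lt(abs(f$slope - 8e-8), 4 * f$slope_se)
  expect_lt(f$p_value, 1e-6)
  expect_equal(slope_per_bp(f, 100), f$slope / 100)
})

test_that("age interaction is exactly zero for indistinguishable cohorts", {
  x <- 1:30
  tab <- freq_table(x, 1e-6 + 4e-8 * x)
  f <- fit_age_interaction(tab, tab, x)
  cf <- f$coefficients
  expect_equal(cf$estimate[cf$term == "beta_age"], 0, tolerance = 1e-15)
  expect_equal(cf$estimate[cf$term == "beta_binxage"], 0, tolerance = 1e-15)

  # noisy but identical tables: symmetry still forces both terms to zero
  set.seed(9)
  tabn <- freq_table(x, 1e-6 + 4e-8 * x + rnorm(30, 0, 2e-7))
  fn <- fit_age_interaction(tabn, tabn, x)
  cfn <- fn$coefficients
  expect_lt(abs(cfn$estimate[cfn$term == "beta_age"]), 1e-12)
  expect_lt(abs(cfn$estimate[cfn$term == "beta_binxage"]), 1e-14)
})

test_that("a constructed slope difference is recovered exactly", {
  x <- 1:40
  delta <- 4e-8
  young <- freq_table(x, 2e-6 + 4e-8 * x)
  old <- freq_table(x, 2e-6 + (4e-8 + delta) * x)
  f <- fit_age_interaction(young, old, x)
  cf <- f$coefficients
  expect_equal(cf$estimate[cf$term == "beta_binxage"], delta,
               tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "beta_bin"], 4e-8, tolerance = 1e-10)

  expect_error(fit_age_interaction(young, old[1:20, ], x), "bin schemes")
})

test_that("simulated age-split cohorts recover the injected slope ratio", {
  b <- default_base_rates(); b[] <- 1.6e-6
  g <- default_gradient_slopes(); g[] <- 0; g["G>A"] <- 4e-8
  cfg <- simulation_config(base_rates = b, gradient_slopes = g,
                           age_multipliers = c(young = 1, old = 2),
                           n_samples = c(young = 10, old = 10),
                           mean_depth = 1e4, classes = "G>A")
  sim <- simulate_mutation_dataset(cfg, seed = 123)
  young <- sim$records[sim$records$age_group == "young", ]
  old <- sim$records[sim$records$age_group == "old", ]
  ids <- sim$depths$sample_ids
  ty <- binned_frequency(young, subset_samples(sim$depths,
                                               grep("young", ids, value = TRUE)),
                         sim$genome, sim$bins, "G>A")
  to <- binned_frequency(old, subset_samples(sim$depths,
                                             grep("old", ids, value = TRUE)),
                         sim$genome, sim$bins, "G>A")
  f <- fit_age_interaction(ty, to, arc_bin_range(mouse_mt_arcs(), "major"),
                           class = "G>A")
  cf <- f$coefficients
  est <- cf$estimate[cf$term == "beta_binxage"]
  se <- cf$se[cf$term == "beta_binxage"]
  # truth: old slope 8e-8, young 4e-8, interaction 4e-8
  expect_gt(est, 0)
  expect_lt(abs(est - 4e-8), 4 * se)
})
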