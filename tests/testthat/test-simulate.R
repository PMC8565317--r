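# The forward simulator: determinism, validation, and closed-form
# calibration against its own injected truth.

test_that("the generator is seed-deterministic", {
  cfg <- quick_config(n_samples = 3L, depth = 2e3)
  a <- simulate_mutation_dataset(cfg, seed = 1)
  b <- simulate_mutation_dataset(cfg, seed = 1)
  expect_identical(a$records, b$records)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_mutation_dataset(cfg, seed = 2)
  expect_false(identical(a$records, c2$records))
})

test_that("infeasible rate configurations are rejected at construction", {
  b <- default_base_rates(); g <- default_gradient_slopes()
  g["G>A"] <- 0.9  # baseline + slope * bin leaves [0, 1] inside the arcs
  expect_error(simulation_config(base_rates = b, gradient_slopes = g),
               "invalid config")
  g["G>A"] <- -1e-5  # negative rate at high bins
  expect_error(simulation_config(base_rates = b, gradient_slopes = g),
               "invalid config")
  b["G>A"] <- -1e-9
  expect_error(simulation_config(base_rates = b,
                                 gradient_slopes = default_gradient_slopes()),
               "rates")
})

test_that("empirical frequencies converge to the injected rates", {
  # 10-bin toy at extreme depth: per-bin frequency within 1% of rate(bin)
  b <- default_base_rates(); b[] <- 1e-4
  g <- default_gradient_slopes(); g[] <- 0
  cfg <- simulation_config(genome_length = 1000, bin_size = 100,
                           arcs = arc_definitions(minor = c(1, 4),
                                                  major = c(6, 9),
                                                  mcr = c(10, 10)),
                           base_rates = b, gradient_slopes = g,
                           age_multipliers = c(adult = 1),
                           n_samples = c(adult = 1), mean_depth = 1e7,
                           base_composition = c(A = 0.001, C = 0.001,
                                                G = 0.997, T = 0.001),
                           classes = "G>A")
  sim <- simulate_mutation_dataset(cfg, seed = 71)
  tab <- binned_frequency(sim$records, sim$depths, sim$genome, sim$bins,
                          "G>A")
  expect_true(all(abs(tab$frequency - 1e-4) / 1e-4 < 0.01))
})

test_that("total mutation counts match the closed-form expectation", {
  cfg <- quick_config(n_samples = 2L, depth = 2e3)
  tot <- numeric(100)
  expected <- NULL
  for (i in 1:100) {
    sim <- simulate_mutation_dataset(cfg, seed = 7000 + i)
    tot[i] <- nrow(sim$records)
    expected <- sum(sim$truth$expected_counts)
  }
  # expectation is the same every replicate up to the random genome's base
  # layout; Poisson-scale spread around it
  se <- sd(tot) / sqrt(100)
  expect_lt(abs(mean(tot) - expected), 4 * se + 0.05 * expected)
})

test_that("a flat generator yields slopes centered on zero", {
  cfg <- quick_config(slope = 0, n_samples = 4L, depth = 5e3,
                      baseline = 5e-6)
  cover <- 0L
  for (i in 1:40) {
    sim <- simulate_mutation_dataset(cfg, seed = 7100 + i)
    tab <- binned_frequency(sim$records, sim$depths, sim$genome,
                            sim$bins, "G>A")
    f <- suppressWarnings(
      fit_arc_gradient(tab, arc_bin_range(mouse_mt_arcs(), "major"),
                       class = "G>A", arc = "major")
    )
    if (abs(f$slope) <= 3 * f$slope_se) cover <- cover + 1L
  }
  expect_gte(cover / 40, 0.9)
})

test_that("hotspot windows validate folds and honor their truth", {
  win <- simulate_hotspot_window(20, 1e-4, rep(1, 20), bin_depth = 1e6,
                                 seed = 72)
  expect_length(win$counts, 20)
  expect_true(all(abs(win$counts - 100) < 5 * sqrt(100)))
  expect_error(simulate_hotspot_window(20, 1e-4, rep(-1, 20)),
               "non-negative")
  expect_error(simulate_hotspot_window(20, 0.5, rep(3, 20)), "exceeds 1")
})

test_that("species sets honor their drawn slopes and determinism", {
  a <- simulate_species_set(10, arc_length = 4000, seed = 73)
  b <- simulate_species_set(10, arc_length = 4000, seed = 73)
  expect_identical(a$truth, b$truth)
  expect_identical(a$species[[4]]$sequence, b$species[[4]]$sequence)
  # a deterministic mirrored pair yields rho -> -1
  m <- simulate_species_set(12, arc_length = 30000, slope_sd = 0.04,
                            anticorrelation = -1, seed = 74)
  grads <- lapply(m$species, species_gradient)
  out <- cross_species_anticorrelation(grads)
  expect_lt(out$rho, -0.8)
  expect_error(simulate_species_set(1), "at least 2")
})
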