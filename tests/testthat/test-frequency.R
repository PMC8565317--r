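# Depth-weighted binned mutation frequency and its conservation laws.

test_that("VAF filter is strict at the cutoff and validates its input", {
  rec <- records_of("s1", 1:3, "G>A", vaf = c(0.005, 0.01, 0.5))
  out <- filter_by_vaf(rec, 0.01)
  expect_equal(out$records$vaf, 0.005)
  expect_equal(out$n_rejected, 2L)

  empty <- filter_by_vaf(rec[0, ], 0.01)
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$n_rejected, 0L)

  bad <- rec; bad$vaf[1] <- 1.5
  expect_error(filter_by_vaf(bad), "malformed")
})

test_that("binned frequency is the ratio of pooled sums", {
  # one 100-bp all-G bin; two samples with depths 10 and 40 per position
  # give S = (1,000, 4,000); counts (2, 3) give F = 5/5,000 = 1e-3
  g <- mono_genome("G", 100)
  d <- depth_profile(cbind(s1 = rep(10, 100), s2 = rep(40, 100)))
  rec <- rbind(records_of("s1", c(5, 50), "G>A"),
               records_of("s2", c(10, 20, 30), "G>A"))
  bins <- tile_bins(100, 100)
  tab <- binned_frequency(rec, d, g, bins, classes = "G>A")
  expect_equal(tab$mutation_count, 5)
  expect_equal(tab$mutable_depth, 5000)
  expect_equal(tab$frequency, 1e-3)

  # zero numerator with positive depth is 0, not missing
  tab0 <- binned_frequency(rec[0, ], d, g, bins, classes = "G>A")
  expect_equal(tab0$frequency, 0)
  # zero denominator is missing, not 0
  tabA <- binned_frequency(rec[0, ], d, g, bins, classes = "A>G")
  expect_true(is.na(tabA$frequency))

  # single sample direct division
  d1 <- depth_profile(matrix(1000, 100, 1), "s1")
  tab1 <- binned_frequency(records_of("s1", 7, "G>A"), d1, g, bins, "G>A")
  expect_equal(tab1$frequency, 1 / 1e5)
})

test_that("counts are conserved across bins and pooling order is irrelevant", {
  g <- rand_genome(600, seed = 21)
  bins <- tile_bins(600, 50)
  set.seed(22)
  gpos <- positions_of(g, "G")
  tpos <- positions_of(g, "T")
  rec <- rbind(
    records_of("s1", sample(gpos, 30, replace = TRUE), "G>A"),
    records_of("s2", sample(gpos, 20, replace = TRUE), "G>A"),
    records_of("s1", sample(tpos, 25, replace = TRUE), "T>C"),
    records_of("s2", sample(tpos, 15, replace = TRUE), "T>C")
  )
  d <- depth_profile(cbind(s1 = rpois(600, 500) + 1,
                           s2 = rpois(600, 900) + 1))
  tab <- binned_frequency(rec, d, g, bins)
  # conservation: per-class bin counts sum to the record count
  expect_equal(sum(tab$mutation_count[tab$class == "G>A"]), 50)
  expect_equal(sum(tab$mutation_count[tab$class == "T>C"]), 40)
  expect_equal(sum(tab$mutation_count), nrow(rec))

  # pooling equivalence: ratio of sums, exactly
  recp <- rec; recp$sample_id <- "pool"
  dp <- depth_profile(matrix(rowSums(d$depth), ncol = 1), "pool")
  tabp <- binned_frequency(recp, dp, g, bins)
  expect_equal(tab$frequency, tabp$frequency, tolerance = 0)
  expect_equal(tab$mutable_depth, tabp$mutable_depth, tolerance = 0)
})

test_that("adding one mutation raises only its own bin", {
  g <- mono_genome("G", 400)
  bins <- tile_bins(400, 100)
  d <- const_depths(400, "s1", 1000)
  rec <- records_of("s1", c(10, 150, 350), "G>A")
  t1 <- binned_frequency(rec, d, g, bins, "G>A")
  t2 <- binned_frequency(rbind(rec, records_of("s1", 160, "G>A")),
                         d, g, bins, "G>A")
  expect_gt(t2$frequency[2], t1$frequency[2])
  expect_equal(t2$frequency[-2], t1$frequency[-2])
})

test_that("inconsistent records are rejected with their coordinates", {
  g <- mono_genome("G", 100)
  bins <- tile_bins(100, 50)
  d <- depth_profile(matrix(c(rep(100, 99), 0), ncol = 1), "s1")
  expect_error(
    binned_frequency(records_of("s1", 100, "G>A"), d, g, bins, "G>A"),
    "position 100.*zero|zero.*position 100"
  )
  # wild-type base must match the reference
  expect_error(
    binned_frequency(records_of("s1", 5, "A>G"), d, g, bins, "A>G"),
    "disagrees"
  )
})

test_that("binned frequency is rotation invariant", {
  g <- rand_genome(600, seed = 31)
  bins <- tile_bins(600, 50)
  set.seed(32)
  d <- depth_profile(cbind(s1 = rpois(600, 800) + 1,
                           s2 = rpois(600, 400) + 1))
  rec <- rbind(records_of("s1", sample(positions_of(g, "G"), 40, TRUE), "G>A"),
               records_of("s2", sample(positions_of(g, "C"), 30, TRUE), "C>T"))
  tab <- binned_frequency(rec, d, g, bins)

  rot <- rotate_reference(g, 100)  # two whole bins
  newpos <- rot$to_rotated(seq_len(600))
  d2m <- d$depth
  d2m[newpos, ] <- d$depth
  rec2 <- rec
  rec2$position <- rot$to_rotated(rec$position)
  tab2 <- binned_frequency(rec2, depth_profile(d2m, d$sample_ids),
                           rot$genome, bins)
  # rotated bin k covers original bin k+2 (mod 12)
  remap <- ((bins$index - 1 + 2) %% 12) + 1
  for (cl in unique(tab$class)) {
    a <- tab[tab$class == cl, ]
    b <- tab2[tab2$class == cl, ]
    expect_equal(b$frequency, a$frequency[remap], tolerance = 0)
  }
})

test_that("leave-one-out removes one group's records and samples", {
  g <- mono_genome("G", 200)
  bins <- tile_bins(200, 100)
  d <- depth_profile(cbind(a1 = rep(100, 200), b1 = rep(300, 200)))
  rec <- rbind(records_of("a1", c(5, 15), "G>A", tissue = "heart"),
               records_of("b1", c(150, 160, 170), "G>A", tissue = "liver"))
  loo <- leave_one_out(rec, d, g, bins, group_field = "tissue",
                       classes = "G>A")
  expect_named(loo, c("heart", "liver"))
  # holding out heart leaves liver's data alone
  expect_equal(loo$heart$mutation_count, c(0, 3))
  expect_equal(loo$heart$mutable_depth, rep(300 * 100, 2))
  expect_equal(loo$liver$mutation_count, c(2, 0))
  expect_error(leave_one_out(rec[rec$tissue == "heart", ], d, g, bins,
                             classes = "G>A"), "2 distinct")

  # eight groups yield eight reduced tables
  rec8 <- do.call(rbind, lapply(1:8, function(i) {
    records_of(paste0("s", i), i, "G>A", tissue = paste0("tis", i))
  }))
  d8 <- const_depths(200, paste0("s", 1:8), 50)
  loo8 <- leave_one_out(rec8, d8, g, bins, group_field = "tissue",
                        classes = "G>A")
  expect_length(loo8, 8L)
  expect_true(all(vapply(loo8, function(t) sum(t$mutation_count),
                         numeric(1)) == 7))
})

test_that("cohort summary reproduces count arithmetic", {
  rec <- rbind(
    records_of(paste0("y", rep(1:4, times = c(3, 3, 2, 2))), 1, "G>A",
               age_group = "young"),
    records_of(paste0("o", rep(1:4, times = c(5, 5, 5, 5))), 1, "G>A",
               age_group = "old")
  )
  s <- mutation_summary(rec, genome_length = 1000)
  expect_equal(s$total_mutations, 30L)
  expect_equal(s$groups$n_mutations[s$groups$group == "young"], 10L)
  expect_equal(s$mean_per_sample, 30 / 8)
  expect_equal(s$density_per_bp, 30 / 8 / 1000)
})
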