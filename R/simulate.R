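# Forward simulator of the asynchronous strand-displacement deamination
# model. The mechanistic knob is deliberately minimal: each class's per-base
# mutation rate is linear in the bin coordinate within the replication arcs
# (flat elsewhere and for non-gradient classes), scaled by an age
# multiplier — exactly the structure the downstream fits assume. Mutation
# counts are Binomial(depth, rate) per position, per sample.

#' Default per-class baseline rates (mutations per duplex base)
#'
#' Presets echoing duplex-sequencing somatic mtDNA spectra: transition
#' baselines of order 1e-6, transversions of order 1e-7. These are presets,
#' not measurements.
#' @return Named numeric vector over the 12 classes.
#' @export
default_base_rates <- function() {
  r <- stats::setNames(rep(8e-8, 12), mutation_classes())
  r["G>A"] <- 1.6e-6
  r["C>T"] <- 1.6e-6
  r["T>C"] <- 4e-7
  r["A>G"] <- 4e-7
  r
}

#' Default per-class gradient slopes (frequency per bin, young scale)
#'
#' Nonzero only for the reference-strand G>A and T>C transitions, whose
#' deamination-driven gradients the strand-displacement model predicts;
#' magnitudes echo fitted somatic slopes (order 1e-8 per 100-bp bin).
#' @return Named numeric vector over the 12 classes.
#' @export
default_gradient_slopes <- function() {
  g <- stats::setNames(rep(0, 12), mutation_classes())
  g["G>A"] <- 3e-8
  g["T>C"] <- 5e-9
  g
}

#' Simulation configuration
#'
#' Validates and freezes the generative model: for a class with wild-type
#' base X, a position p in arc bin b, and a sample with age multiplier m,
#' the per-duplex-base mutation rate is `m * (b_N + g_N * b)`; outside the
#' arcs (Ori_L gap, mCR) the rate is the flat `m * b_N`. Defaults describe
#' the paired-cohort mouse design: 16,299-bp genome, 100-bp bins, 40 young
#' + 45 old samples, constant duplex depth 1e4 per position per sample,
#' old-age multiplier 2.5 (so the old G>A major-arc slope is 7.5e-8 per
#' bin), giving expected mutation burdens of roughly 230 (young) and 580
#' (old) per sample, i.e. a mean density of about 0.025 mutations/bp.
#'
#' @param genome_length,bin_size,arcs Genome geometry (mouse defaults).
#' @param base_rates Named per-class baselines `b_N` (see
#'   [default_base_rates()]).
#' @param gradient_slopes Named per-class slopes `g_N` per bin (see
#'   [default_gradient_slopes()]).
#' @param age_multipliers Named multipliers, one per age group.
#' @param n_samples Named sample counts, aligned with `age_multipliers`.
#' @param mean_depth Mean duplex depth per position per sample.
#' @param depth_dispersion Negative-binomial size for per-position depth;
#'   `Inf` (default) means constant depth.
#' @param base_composition Reference base probabilities used to draw the
#'   synthetic genome sequence (mouse-like L-strand composition).
#' @param tissues Tissue labels cycled across samples.
#' @param classes Classes to simulate (default all 12).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 16299L, bin_size = 100L,
                              arcs = mouse_mt_arcs(),
                              base_rates = default_base_rates(),
                              gradient_slopes = default_gradient_slopes(),
                              age_multipliers = c(young = 1, old = 2.5),
                              n_samples = c(young = 40L, old = 45L),
                              mean_depth = 1e4,
                              depth_dispersion = Inf,
                              base_composition = c(A = 0.346, C = 0.243,
                                                   G = 0.123, T = 0.288),
                              tissues = c("heart", "liver", "kidney",
                                          "muscle", "cerebellum",
                                          "hippocampus", "retina",
                                          "eyecup"),
                              classes = mutation_classes()) {
  if (!all(classes %in% mutation_classes())) stop("unknown mutation class")
  if (!all(classes %in% names(base_rates)) ||
      !all(classes %in% names(gradient_slopes))) {
    stop("base_rates and gradient_slopes must cover every simulated class")
  }
  if (!identical(sort(names(age_multipliers)), sort(names(n_samples)))) {
    stop("age_multipliers and n_samples must use the same group names")
  }
  if (any(base_rates < 0) || any(base_rates > 1)) {
    stop("invalid config: baseline rates must lie in [0, 1]")
  }
  if (mean_depth <= 0) stop("invalid config: mean_depth must be positive")
  bins <- tile_bins(genome_length, bin_size)
  arc_bins <- bins$index[assign_arc(bins$index, arcs) %in% c("minor", "major")]
  for (cl in classes) {
    for (m in age_multipliers) {
      rates <- m * (base_rates[cl] + gradient_slopes[cl] * arc_bins)
      if (any(rates < 0) || any(rates > 1)) {
        stop("invalid config: class ", cl,
             " rate leaves [0, 1] within the arcs")
      }
    }
  }
  structure(list(genome_length = as.integer(genome_length),
                 bin_size = as.integer(bin_size), arcs = arcs,
                 base_rates = base_rates,
                 gradient_slopes = gradient_slopes,
                 age_multipliers = age_multipliers,
                 n_samples = n_samples, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 base_composition = base_composition / sum(base_composition),
                 tissues = tissues, classes = classes),
            class = "simulation_config")
}

#' Random mtDNA-like reference sequence
#' @param length Sequence length in bp.
#' @param base_probs Base sampling probabilities (mouse-like default).
#' @return A single sequence string (uses the current RNG state).
#' @export
random_mt_sequence <- function(length,
                               base_probs = c(A = 0.346, C = 0.243,
                                              G = 0.123, T = 0.288)) {
  paste(sample(BASES, length, replace = TRUE,
               prob = base_probs[BASES] / sum(base_probs)),
        collapse = "")
}

#' Simulate a somatic mutation dataset with known truth
#'
#' Draws a reference sequence, per-sample depth profiles, and per-position
#' per-class mutation counts `Binomial(depth, rate)` under the linear
#' arc-coordinate rate model of [simulation_config()]. Each mutant
#' molecule becomes one variant record with VAF `1/depth` at its site
#' (single-molecule calls, so everything survives the 1% VAF filter at
#' realistic depths). The injected truth is returned alongside the data.
#'
#' @param config A [simulation_config()].
#' @param seed Optional RNG seed (fully determines the output).
#' @return A list: `records` (variant `data.frame` with `sample_id`,
#'   `position`, `ref`, `alt`, `vaf`, `tissue`, `age_group`, `class`),
#'   `depths` ([depth_profile()]), `genome` ([circular_genome()]), `bins`,
#'   `truth` (list of injected `base_rates`, `gradient_slopes`,
#'   `age_multipliers`, and the closed-form `expected_counts` matrix,
#'   classes x samples), and `config`.
#' @export
simulate_mutation_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$genome_length
  seqstr <- random_mt_sequence(L, config$base_composition)
  ch <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  bins <- tile_bins(L, config$bin_size)
  bi <- bin_of(seq_len(L), bins)
  in_arc_bin <- assign_arc(bins$index, config$arcs) %in% c("minor", "major")
  in_arc <- in_arc_bin[bi]
  ages <- rep(names(config$n_samples), config$n_samples)
  n <- length(ages)
  ids <- sprintf("s%03d_%s", seq_len(n), ages)
  tissue <- rep_len(config$tissues, n)
  depth <- if (is.finite(config$depth_dispersion)) {
    matrix(stats::rnbinom(L * n, mu = config$mean_depth,
                          size = config$depth_dispersion), nrow = L)
  } else {
    matrix(config$mean_depth, nrow = L, ncol = n)
  }
  depths <- depth_profile(depth, ids)
  mult <- config$age_multipliers[ages]
  expected <- matrix(0, nrow = length(config$classes), ncol = n,
                     dimnames = list(config$classes, ids))
  acc <- list()
  ai <- 0L
  for (cl in config$classes) {
    rb <- substr(cl, 1L, 1L)
    ab <- substr(cl, 3L, 3L)
    pos <- which(ch == rb)
    if (!length(pos)) next
    r0 <- config$base_rates[[cl]] +
      ifelse(in_arc[pos], config$gradient_slopes[[cl]] * bi[pos], 0)
    for (j in seq_len(n)) {
      dj <- depth[pos, j]
      p <- pmin(mult[j] * r0, 1)
      expected[cl, j] <- sum(dj * p)
      cnt <- stats::rbinom(length(pos), dj, p)
      hit <- which(cnt > 0L)
      if (length(hit)) {
        ai <- ai + 1L
        hp <- rep(pos[hit], cnt[hit])
        acc[[ai]] <- data.frame(
          sample_id = ids[j], position = hp, ref = rb, alt = ab,
          vaf = 1 / depth[hp, j], tissue = tissue[j],
          age_group = ages[j], class = cl
        )
      }
    }
  }
  records <- if (length(acc)) do.call(rbind, acc) else {
    data.frame(sample_id = character(), position = integer(),
               ref = character(), alt = character(), vaf = numeric(),
               tissue = character(), age_group = character(),
               class = character())
  }
  rownames(records) <- NULL
  genome <- circular_genome("sim_mt", L, sequence = seqstr)
  truth <- list(base_rates = config$base_rates[config$classes],
                gradient_slopes = config$gradient_slopes[config$classes],
                age_multipliers = config$age_multipliers,
                expected_counts = expected)
  list(records = records, depths = depths, genome = genome, bins = bins,
       truth = truth, config = config)
}

#' Simulate a control-region scan window
#'
#' Per-bin counts `Binomial(depth, rate * fold)`; fold-changes above 1
#' plant hot-spots, a fold of 0 plants a cold-spot.
#'
#' @param n_bins Number of bins K (default 20).
#' @param baseline_rate Per-base mutation rate.
#' @param folds Per-bin fold-changes (length K, non-negative).
#' @param bin_depth Mutable-base depth per bin (scalar or length K).
#' @param seed Optional RNG seed.
#' @return A list: `counts`, `bin_depths`, `truth` (rate and folds).
#' @export
simulate_hotspot_window <- function(n_bins = 20, baseline_rate = 1e-4,
                                    folds = rep(1, n_bins),
                                    bin_depth = 2e5, seed = NULL) {
  if (n_bins < 1) stop("need at least one bin")
  if (length(folds) != n_bins) stop("folds must have length n_bins")
  if (any(folds < 0)) stop("invalid argument: folds must be non-negative")
  bin_depth <- rep_len(bin_depth, n_bins)
  p <- baseline_rate * folds
  if (any(p > 1)) stop("invalid argument: rate * fold exceeds 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rbinom(n_bins, round(bin_depth), p)
  list(counts = counts, bin_depths = bin_depth,
       truth = list(baseline_rate = baseline_rate, folds = folds))
}

#' Simulate a species set with anti-correlated composition slopes
#'
#' Draws per-species (dG, dA) composition slopes from a bivariate normal
#' with the requested correlation (truncated to keep all per-bin base
#' probabilities well inside (0, 1)), then samples each species' arc
#' sequence with per-bin base probabilities following those linear trends.
#' The complementary C/T share takes up the remainder at a fixed ratio.
#'
#' @param n_species Number of species (default 300).
#' @param arc_length Major-arc length in bp per species.
#' @param bin_size Bin width used to define the trends.
#' @param mean_slopes Named mean slopes in percent per bin for the pair,
#'   default `c(G = -0.05, A = 0.05)`.
#' @param slope_sd Per-species slope standard deviation (percent per bin).
#' @param anticorrelation Target correlation between the two slopes.
#' @param base_means Mean base composition around which trends pivot.
#' @param seed Optional RNG seed.
#' @return A list: `species` (list of [species_record()]), `truth`
#'   (`data.frame` of drawn slopes per species).
#' @export
simulate_species_set <- function(n_species = 300, arc_length = 10000,
                                 bin_size = 100,
                                 mean_slopes = c(G = -0.05, A = 0.05),
                                 slope_sd = 0.05, anticorrelation = -0.6,
                                 seed = NULL,
                                 base_means = c(A = 0.32, C = 0.28,
                                                G = 0.15, T = 0.25)) {
  if (n_species < 2) stop("need at least 2 species")
  if (abs(anticorrelation) > 1) stop("correlation must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(ceiling(arc_length / bin_size))
  half <- (B - 1) / 2
  # feasibility: a slope s (%/bin) shifts the probability by s/100 * half at
  # the arc ends; keep every probability above 0.02
  smax <- pmin((base_means[c("G", "A")] - 0.02) * 100 / max(half, 1), 0.25)
  if (any(abs(mean_slopes) >= smax)) {
    stop("invalid config: mean slopes infeasible for this arc length")
  }
  z1 <- stats::rnorm(n_species)
  z2 <- anticorrelation * z1 +
    sqrt(1 - anticorrelation^2) * stats::rnorm(n_species)
  sG <- pmin(pmax(mean_slopes["G"] + slope_sd * z1, -smax["G"]), smax["G"])
  sA <- pmin(pmax(mean_slopes["A"] + slope_sd * z2, -smax["A"]), smax["A"])
  tcen <- seq_len(B) - (B + 1) / 2
  wC <- base_means["C"] / (base_means["C"] + base_means["T"])
  species <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    pG <- base_means["G"] + sG[i] / 100 * tcen
    pA <- base_means["A"] + sA[i] / 100 * tcen
    rem <- 1 - pG - pA
    pC <- rem * wC
    pT <- rem * (1 - wC)
    P <- cbind(A = pA, C = pC, G = pG, T = pT)[rep(seq_len(B),
                                                   each = bin_size), ]
    P <- P[seq_len(arc_length), , drop = FALSE]
    u <- stats::runif(arc_length)
    c1 <- P[, "A"]; c2 <- c1 + P[, "C"]; c3 <- c2 + P[, "G"]
    idx <- 1L + (u > c1) + (u > c2) + (u > c3)
    species[[i]] <- species_record(
      taxon = sprintf("sp%04d", i),
      sequence = paste(BASES[idx], collapse = ""),
      class_label = "synthetic"
    )
  }
  truth <- data.frame(taxon = sprintf("sp%04d", seq_len(n_species)),
                      slope_G = as.numeric(sG), slope_A = as.numeric(sA))
  list(species = species, truth = truth)
}
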