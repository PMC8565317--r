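# Stage 3: composition-aware Monte-Carlo null models. Both tests scatter the
# observed mutation totals across bins with probabilities proportional to
# each bin's mutable-base duplex depth, so the null respects base
# composition and coverage structure.

#' Depth-proportional bin weights for one mutation class
#'
#' The probability weight of bin i is its cumulative wild-type mutable-base
#' depth divided by the cumulative depth of the same base over the whole
#' interval; bins with zero mutable depth get weight zero.
#'
#' @param bin_depths Per-bin mutable-base depths `S_i` over the interval.
#' @param bins Integer bin indices the depths refer to (default
#'   `seq_along(bin_depths)`).
#' @return An object of class `bin_weights`: list with `weights` (sums to
#'   1), `bins`, `total_depth`.
#' @export
compute_bin_weights <- function(bin_depths, bins = seq_along(bin_depths)) {
  if (length(bin_depths) != length(bins)) {
    stop("bin_depths and bins must have equal length")
  }
  if (any(bin_depths < 0)) stop("depths must be non-negative")
  tot <- sum(bin_depths)
  if (tot <= 0) stop("zero total depth over the interval")
  structure(list(weights = bin_depths / tot, bins = as.integer(bins),
                 total_depth = tot),
            class = "bin_weights")
}

#' Permutation test for an observed gradient slope
#'
#' Each replicate scatters the class's `n_mutations` across the interval's
#' bins by a multinomial draw with the depth-proportional `weights`,
#' converts counts to frequencies with the real per-bin denominators,
#' refits the arc regression with the same estimator as the observed
#' analysis, and records the slope. The p-value is the fraction of permuted
#' slopes greater than or equal to the observed slope (one-tailed by
#' design; `two_tailed = TRUE` compares absolute slopes instead). No
#' pseudo-count is added, so the p-value granularity is `1/n_perm`; a raw
#' ratio of 0 prints as `< 1/n_perm`.
#'
#' @param n_mutations Total mutations of the class in the interval.
#' @param weights A [compute_bin_weights()] object over the interval.
#' @param bin_depths Per-bin mutable depths `S_i` (the real denominators),
#'   aligned with `weights$bins`.
#' @param arc_bins Bin indices of the arc the regression is restricted to.
#' @param observed_slope Slope of the observed fit (same estimator).
#' @param n_perm Number of replicates (default 10,000).
#' @param seed Optional RNG seed (recorded in the result).
#' @param estimator `"huber"` (vectorized IRLS matching
#'   [fit_arc_gradient()]) or `"ols"`.
#' @param two_tailed Compare `|slope|` instead of signed slope.
#' @param k Huber tuning constant.
#' @param keep_counts Also return the permuted count matrix.
#' @return Object of class `permutation_test`: `observed`, `n_perm`,
#'   `count_ge`, `p_value`, `seed`, `slopes`, optionally `counts`.
#' @export
gradient_permutation_test <- function(n_mutations, weights, bin_depths,
                                      arc_bins, observed_slope,
                                      n_perm = 10000, seed = NULL,
                                      estimator = c("huber", "ols"),
                                      two_tailed = FALSE, k = 1.345,
                                      keep_counts = FALSE) {
  estimator <- match.arg(estimator)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_mutations < 1) stop("need at least one mutation to permute")
  if (length(bin_depths) != length(weights$weights)) {
    stop("bin_depths must align with the weight vector")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(n_perm, n_mutations, weights$weights)
  usable <- bin_depths > 0 & weights$bins %in% arc_bins
  if (sum(usable) < 3L) stop("insufficient data: fewer than 3 usable arc bins")
  x <- weights$bins[usable]
  Fm <- counts[usable, , drop = FALSE] / bin_depths[usable]
  slopes <- if (estimator == "huber") {
    huber_slope_matrix(x, Fm, k = k)$slope
  } else {
    xc <- x - mean(x)
    as.vector(crossprod(xc, Fm)) / sum(xc^2)
  }
  stat <- if (two_tailed) abs(slopes) else slopes
  obs <- if (two_tailed) abs(observed_slope) else observed_slope
  count_ge <- sum(stat >= obs)
  structure(list(observed = observed_slope, n_perm = as.integer(n_perm),
                 count_ge = count_ge, p_value = count_ge / n_perm,
                 seed = seed, estimator = estimator,
                 two_tailed = two_tailed, slopes = slopes,
                 counts = if (keep_counts) counts else NULL),
            class = "permutation_test")
}

#' Human-readable permutation p-value
#' @param x A `permutation_test`.
#' @return A string; a raw ratio of 0 is shown as `< 1/n_perm`.
#' @export
format_perm_p <- function(x) {
  if (x$count_ge == 0) sprintf("< %g", 1 / x$n_perm) else sprintf("%g", x$p_value)
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed slope = %.4g, p %s (%d of %d permuted slopes >= observed%s)\n",
              x$observed,
              if (x$count_ge == 0) format_perm_p(x) else paste("=", format_perm_p(x)),
              x$count_ge, x$n_perm,
              if (x$two_tailed) ", two-tailed" else ""))
  invisible(x)
}

#' Monte-Carlo hot/cold-spot scan of a control-region window
#'
#' Scatters the window's observed mutation total across its K bins
#' (multinomial, depth-proportional weights) `n_perm` times, retains the
#' per-bin permuted frequency distributions, and draws a two-sided
#' empirical envelope at the Bonferroni-corrected per-bin confidence
#' `1 - family_alpha / K` (K = 20, alpha = 0.05 gives the 99.75% envelope,
#' i.e. a per-bin two-tailed threshold of 0.0025). Bins whose observed
#' frequency exceeds the upper bound are classified `"over"`, below the
#' lower bound `"under"`, else `"none"`. Envelope bounds are nearest-rank
#' empirical quantiles of the permuted frequencies.
#'
#' @param observed_counts Per-bin observed mutation counts (length K).
#' @param bin_depths Per-bin mutable-base depths (length K).
#' @param n_perm Number of Monte-Carlo replicates (default 100,000).
#' @param family_alpha Family-wise two-sided level (default 0.05).
#' @param seed Optional RNG seed.
#' @return A `data.frame` (class `hotspot_scan`) with columns `bin`,
#'   `observed_count`, `depth`, `observed_freq`, `sim_mean`, `lower`,
#'   `upper`, `classification`; attributes `n_perm`, `family_alpha`,
#'   `per_bin_alpha`, `envelope_level`, `n_mutations`, `seed`.
#' @export
mcr_hotspot_scan <- function(observed_counts, bin_depths, n_perm = 100000,
                             family_alpha = 0.05, seed = NULL) {
  K <- length(observed_counts)
  if (K < 1L) stop("insufficient data: no bins")
  if (length(bin_depths) != K) stop("bin_depths must have length K")
  n <- sum(observed_counts)
  if (n < 1) stop("insufficient data: no mutations in the window")
  w <- compute_bin_weights(bin_depths)$weights
  if (!is.null(seed)) set.seed(seed)
  cm <- stats::rmultinom(n_perm, n, w)
  tail_p <- family_alpha / K / 2
  lower <- numeric(K); upper <- numeric(K); mu <- numeric(K)
  obsF <- ifelse(bin_depths > 0, observed_counts / bin_depths, NA_real_)
  for (i in seq_len(K)) {
    if (bin_depths[i] > 0) {
      f <- cm[i, ] / bin_depths[i]
      lower[i] <- stats::quantile(f, probs = tail_p, type = 1, names = FALSE)
      upper[i] <- stats::quantile(f, probs = 1 - tail_p, type = 1,
                                  names = FALSE)
      mu[i] <- mean(f)
    } else {
      lower[i] <- NA_real_; upper[i] <- NA_real_; mu[i] <- NA_real_
    }
  }
  cls <- rep("none", K)
  cls[!is.na(obsF) & !is.na(upper) & obsF > upper] <- "over"
  cls[!is.na(obsF) & !is.na(lower) & obsF < lower] <- "under"
  out <- data.frame(bin = seq_len(K), observed_count = observed_counts,
                    depth = bin_depths, observed_freq = obsF, sim_mean = mu,
                    lower = lower, upper = upper, classification = cls)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "family_alpha") <- family_alpha
  attr(out, "per_bin_alpha") <- family_alpha / K
  attr(out, "envelope_level") <- 1 - family_alpha / K
  attr(out, "n_mutations") <- n
  attr(out, "seed") <- seed
  class(out) <- c("hotspot_scan", "data.frame")
  out
}
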