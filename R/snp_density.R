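# Stage 4: population-SNP and tumor-variant density gradients. Density
# denominators come from the reference sequence alone (wild-type base counts
# per bin), so they are identical across datasets on the same genome; only
# preprocessing differs between SNP mode and tumor mode.

#' Preprocess a population SNP list
#'
#' Applies the rare-variant filter (population frequency `<= freq_max`,
#' inclusive bound; default 1:1000) and collapses recurrent entries —
#' identical (position, ref, alt) triples — to a single de novo event.
#' Records without a frequency pass only when the frequency filter is
#' disabled. The operation is idempotent.
#'
#' @param snps `data.frame` with columns `position`, `ref`, `alt` and
#'   optionally `frequency`.
#' @param freq_max Inclusive frequency ceiling; `NULL` disables the filter.
#' @param collapse_recurrent Collapse duplicate variants to one event.
#' @return Filtered records with an `n_observed` multiplicity column;
#'   attributes `n_removed_freq` and `n_collapsed`.
#' @export
preprocess_snps <- function(snps, freq_max = 0.001,
                            collapse_recurrent = TRUE) {
  n_removed <- 0L
  out <- snps
  if (!is.null(freq_max)) {
    f <- if ("frequency" %in% names(out)) out$frequency else {
      rep(NA_real_, nrow(out))
    }
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("population frequencies must lie in [0, 1]")
    }
    keep <- !is.na(f) & f <= freq_max
    n_removed <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  n_collapsed <- 0L
  if (collapse_recurrent && nrow(out)) {
    key <- paste(out$position, out$ref, out$alt, sep = ":")
    mult <- as.vector(table(key)[key])
    first <- !duplicated(key)
    n_collapsed <- sum(!first)
    out <- out[first, , drop = FALSE]
    out$n_observed <- mult[first]
  } else if (!"n_observed" %in% names(out)) {
    out$n_observed <- rep(1L, nrow(out))
  }
  rownames(out) <- NULL
  attr(out, "n_removed_freq") <- n_removed
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' Per-bin variant density normalized by wild-type base content
#'
#' For each bin and class, counts variants of the class and divides by the
#' number of the class's wild-type bases in the bin's reference
#' subsequence (e.g. #G>A / #G). Bins containing no wild-type base carry
#' `NA` density (undefined, not zero). Variants whose recorded reference
#' base disagrees with the genome sequence are excluded with a warning and
#' counted in the `n_ref_mismatch` attribute.
#'
#' @param variants `data.frame` with `position`, `ref`, `alt` (a `class`
#'   column is computed if absent); a [preprocess_snps()] output or a tumor
#'   variant table.
#' @param genome A [circular_genome()] with sequence.
#' @param bins A [tile_bins()] tiling.
#' @param classes Mutation classes (default all 12).
#' @return `data.frame` (class `density_table`) with columns `class`,
#'   `bin`, `start`, `end`, `variant_count`, `base_count`, `density`.
#' @export
density_per_bin <- function(variants, genome, bins,
                            classes = mutation_classes()) {
  if (!"class" %in% names(variants)) variants <- classify_records(variants)
  ch <- genome_bases(genome)
  nb <- nrow(bins)
  n_mismatch <- 0L
  if (nrow(variants)) {
    pos <- as.integer(variants$position)
    if (any(pos < 1L) || any(pos > genome$length)) {
      stop("variant position outside the genome")
    }
    wt <- substr(variants$class, 1L, 1L)
    bad <- ch[pos] != wt
    n_mismatch <- sum(bad)
    if (n_mismatch) {
      warning("excluded ", n_mismatch,
              " variant(s) whose ref base disagrees with the reference")
      variants <- variants[!bad, , drop = FALSE]
    }
  }
  binidx <- bin_of(seq_len(genome$length), bins)
  out <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    rb <- substr(cl, 1L, 1L)
    nbase <- tabulate(binidx[ch == rb], nbins = nb)
    cnt <- numeric(nb)
    if (nrow(variants)) {
      vp <- variants$position[variants$class == cl]
      if (length(vp)) cnt <- tabulate(bin_of(vp, bins), nbins = nb)
    }
    out[[k]] <- data.frame(class = cl, bin = bins$index, start = bins$start,
                           end = bins$end, variant_count = cnt,
                           base_count = nbase,
                           density = ifelse(nbase > 0, cnt / nbase,
                                            NA_real_))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "bins") <- bins
  attr(tab, "n_ref_mismatch") <- n_mismatch
  class(tab) <- c("density_table", "data.frame")
  tab
}

#' Density gradient over an arc
#'
#' Either a robust slope (delegating to [fit_arc_gradient()] on the
#' density column) or a Spearman rank correlation of density against bin
#' index with a two-sided p-value.
#'
#' @param table A [density_per_bin()] table (one class, or pass `class`).
#' @param arc_bins Integer vector of arc bin indices.
#' @param method `"spearman"` or `"robust_slope"`.
#' @param class Optional class filter.
#' @return For `"spearman"` a list (`method`, `rho`, `p_value`, `n_bins`);
#'   for `"robust_slope"` an `arc_fit`.
#' @export
density_gradient <- function(table, arc_bins,
                             method = c("spearman", "robust_slope"),
                             class = NULL) {
  method <- match.arg(method)
  if (method == "robust_slope") {
    return(fit_arc_gradient(table, arc_bins, response = "density",
                            class = class))
  }
  sub <- table
  if ("class" %in% names(sub) && !is.null(class)) {
    sub <- sub[sub$class == class, , drop = FALSE]
  }
  if ("class" %in% names(sub) && length(unique(sub$class)) > 1L) {
    stop("filter the table to a single class")
  }
  sub <- sub[sub$bin %in% arc_bins & is.finite(sub$density), , drop = FALSE]
  if (nrow(sub) < 3L) stop("insufficient data: fewer than 3 usable bins")
  ct <- suppressWarnings(
    stats::cor.test(sub$bin, sub$density, method = "spearman", exact = FALSE)
  )
  list(method = "spearman", rho = unname(ct$estimate),
       p_value = ct$p.value, n_bins = nrow(sub))
}
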