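# Stage 5: genome-composition gradients. A sustained G>A / T>C mutational
# pressure on the reference strand predicts, over evolutionary time, a
# spatially dependent depletion of dG/dT and enrichment of dA/dC along the
# major arc; complementary-base composition slopes should therefore be
# anti-correlated across species.

#' Per-bin nucleotide composition
#'
#' Percent A/C/G/T per bin, computed over the bin's unambiguous bases;
#' ambiguity codes are tracked separately and excluded from the
#' denominator. Entirely ambiguous bins are flagged missing (`NA`
#' percents). Per bin, the four percents sum to 100.
#'
#' @param sequence A string or a [circular_genome()] with sequence.
#' @param bin_size Bin width in bp (default 100).
#' @return `data.frame` with columns `bin`, `start`, `end`, `pct_A`,
#'   `pct_C`, `pct_G`, `pct_T`, `n_unambiguous`, `n_ambiguous`.
#' @export
composition_per_bin <- function(sequence, bin_size = 100) {
  seqstr <- if (inherits(sequence, "circular_genome")) {
    if (is.null(sequence$sequence)) stop("genome has no sequence")
    sequence$sequence
  } else {
    toupper(as.character(sequence))
  }
  L <- nchar(seqstr)
  if (L < 1L) stop("empty sequence")
  if (L < bin_size) stop("sequence shorter than one bin")
  bins <- tile_bins(L, bin_size)
  ch <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  bi <- bin_of(seq_len(L), bins)
  nb <- nrow(bins)
  cnt <- sapply(BASES, function(b) tabulate(bi[ch == b], nbins = nb))
  if (nb == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, BASES))
  denom <- rowSums(cnt)
  n_amb <- bins$width - denom
  pct <- 100 * cnt / ifelse(denom > 0, denom, NA_real_)
  out <- data.frame(bin = bins$index, start = bins$start, end = bins$end,
                    pct_A = pct[, "A"], pct_C = pct[, "C"],
                    pct_G = pct[, "G"], pct_T = pct[, "T"],
                    n_unambiguous = denom, n_ambiguous = n_amb)
  rownames(out) <- NULL
  out
}

#' One species' mtDNA record
#'
#' @param taxon Species name or accession.
#' @param sequence mtDNA sequence string (reference/light strand).
#' @param arc Length-2 vector of 1-based major-arc bounds; `end < start`
#'   wraps through the origin. `NULL` uses the whole sequence.
#' @param class_label Optional taxonomic class label (metadata filter).
#' @return An object of class `species_record`.
#' @export
species_record <- function(taxon, sequence, arc = NULL,
                           class_label = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("empty sequence")
  structure(list(taxon = taxon, sequence = sequence, arc = arc,
                 class_label = class_label),
            class = "species_record")
}

#' Composition gradient of one species' major arc
#'
#' Extracts the major-arc subsequence, bins it, and fits percent
#' composition against bin index for each base type. Ordinary least
#' squares is the default; the Huber estimator used for mutation
#' gradients is available by flag (single shared code path via
#' [fit_arc_gradient()]).
#'
#' @param species A [species_record()].
#' @param bin_size Bin width in bp (default 100).
#' @param estimator `"ols"` or `"huber"`.
#' @return Object of class `composition_gradient`: list with `taxon`,
#'   `class_label`, `n_bins`, and `gradients` (`data.frame` of `base`,
#'   `slope` in percent per bin, `se`, `r` Pearson correlation,
#'   `p_value`).
#' @export
species_gradient <- function(species, bin_size = 100,
                             estimator = c("ols", "huber")) {
  estimator <- match.arg(estimator)
  arcseq <- if (is.null(species$arc)) {
    species$sequence
  } else {
    extract_circular(species$sequence, species$arc[1], species$arc[2])
  }
  if (nchar(arcseq) < 3L * bin_size) {
    stop("insufficient data: major arc shorter than 3 bins")
  }
  comp <- composition_per_bin(arcseq, bin_size)
  grads <- do.call(rbind, lapply(BASES, function(b) {
    y <- comp[[paste0("pct_", b)]]
    x <- comp$bin
    ok <- is.finite(y)
    y <- y[ok]; x <- x[ok]
    if (length(y) < 3L) {
      return(data.frame(base = b, slope = NA_real_, se = NA_real_,
                        r = NA_real_, p_value = NA_real_))
    }
    if (estimator == "huber") {
      tab <- data.frame(bin = x, frequency = y)
      f <- fit_arc_gradient(tab, x, estimator = "huber")
      slope <- f$slope; se <- f$slope_se; p <- f$p_value
    } else {
      f <- .ols_summary(x, y)
      slope <- f$slope; se <- f$se
      p <- .p_from_t(slope, se, df = f$n - 2)
    }
    syy <- sum((y - mean(y))^2)
    r <- if (syy > 0) {
      sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * syy)
    } else {
      NA_real_
    }
    data.frame(base = b, slope = slope, se = se, r = r, p_value = p)
  }))
  rownames(grads) <- NULL
  structure(list(taxon = species$taxon, class_label = species$class_label,
                 n_bins = nrow(comp), gradients = grads),
            class = "composition_gradient")
}

#' Cross-species anti-correlation of complementary-base slopes
#'
#' Spearman rank correlation, across species, of the composition slopes of
#' a complementary base pair — dG vs dA, or dT vs dC. A graduated G>A
#' (T>C) mutational pressure predicts a negative correlation: species that
#' lose dG faster along the arc gain dA faster.
#'
#' @param gradients A list of [species_gradient()] results, or a
#'   `data.frame` with columns `taxon`, `base`, `slope`.
#' @param pair Length-2 character vector of bases, default `c("G", "A")`.
#' @return A list: `pair`, `rho`, `p_value`, `n_species`.
#' @export
cross_species_anticorrelation <- function(gradients, pair = c("G", "A")) {
  if (is.data.frame(gradients)) {
    df <- gradients
  } else {
    df <- do.call(rbind, lapply(gradients, function(g) {
      cbind(taxon = g$taxon, g$gradients[, c("base", "slope")])
    }))
  }
  s1 <- df$slope[df$base == pair[1]]
  s2 <- df$slope[df$base == pair[2]]
  if (length(s1) != length(s2)) stop("unbalanced slope vectors")
  ok <- is.finite(s1) & is.finite(s2)
  if (sum(ok) < 5L) stop("insufficient data: need >= 5 species")
  ct <- suppressWarnings(
    stats::cor.test(s1[ok], s2[ok], method = "spearman", exact = FALSE)
  )
  list(pair = paste(pair, collapse = "/"), rho = unname(ct$estimate),
       p_value = ct$p.value, n_species = sum(ok))
}
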