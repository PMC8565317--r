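# Stage 1: VAF filtering and the depth-weighted binned mutation frequency.
#
# For bin i and class N the statistic is
#   F_i = sum_j M_ij / sum_j S_ij
# where M_ij counts class-N mutations of sample j in bin i and S_ij is the
# duplex depth summed over the positions of bin i whose reference base is the
# class's wild-type base. It is a ratio of sums (a depth-weighted mean), not
# a mean of per-sample ratios.

#' Per-sample per-position duplex depth
#'
#' @param depth Numeric matrix (positions x samples) of duplex depth, or a
#'   vector for a single sample. Row r is genome position r.
#' @param sample_ids Optional sample names (default: existing colnames or
#'   `s1..sn`).
#' @return An object of class `depth_profile`: list with `depth` (matrix),
#'   `sample_ids`, `genome_length`.
#' @export
depth_profile <- function(depth, sample_ids = NULL) {
  if (is.vector(depth)) depth <- matrix(depth, ncol = 1L)
  depth <- as.matrix(depth)
  if (any(!is.finite(depth)) || any(depth < 0)) {
    stop("depths must be finite and non-negative")
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(depth)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(depth)))
  }
  if (length(sample_ids) != ncol(depth)) {
    stop("length of sample_ids must match the number of depth columns")
  }
  colnames(depth) <- sample_ids
  structure(list(depth = depth, sample_ids = sample_ids,
                 genome_length = nrow(depth)),
            class = "depth_profile")
}

#' Restrict a depth profile to a subset of samples
#' @param depths A [depth_profile()].
#' @param keep Character vector of sample ids to keep.
#' @return A `depth_profile` over the kept samples.
#' @export
subset_samples <- function(depths, keep) {
  miss <- setdiff(keep, depths$sample_ids)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  depth_profile(depths$depth[, keep, drop = FALSE], keep)
}

#' Filter variant records by variant allele fraction
#'
#' Keeps records with `vaf < vaf_max` (strict inequality: a VAF exactly at
#' the cutoff is rejected). The filter guards against inherited or
#' early-arising variants masquerading as somatic calls.
#'
#' @param records `data.frame` with a `vaf` column in `[0, 1]`.
#' @param vaf_max Exclusive upper bound, default 0.01 (1%).
#' @return A list: `records` (kept rows), `n_rejected`.
#' @export
filter_by_vaf <- function(records, vaf_max = 0.01) {
  if (nrow(records) == 0L) return(list(records = records, n_rejected = 0L))
  v <- records$vaf
  if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
    stop("malformed record: VAF outside [0, 1]")
  }
  keep <- v < vaf_max
  list(records = records[keep, , drop = FALSE], n_rejected = sum(!keep))
}

# per-bin sum of `values` defined on the positions `pos`
.bin_sum <- function(values, pos, bins) {
  out <- numeric(nrow(bins))
  if (length(pos)) {
    s <- rowsum(values, bin_of(pos, bins))
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Depth-normalized binned mutation frequency
#'
#' Computes, for each bin and mutation class, the pooled mutation count
#' `M_i`, the pooled mutable-base depth `S_i` (duplex depth summed over the
#' bin's positions whose reference base is the class's wild-type base, over
#' all samples), and the frequency `F_i = M_i / S_i`. Bins with `S_i = 0`
#' carry `NA` frequency (missing, not zero: an unsequenced bin is not
#' evidence of absence) and are dropped listwise downstream.
#'
#' @param records Variant `data.frame` with columns `sample_id`, `position`,
#'   `ref`, `alt` (plus optional `class`; computed if absent). Records are
#'   assumed already VAF-filtered.
#' @param depths A [depth_profile()] covering the genome.
#' @param genome A [circular_genome()] with sequence.
#' @param bins A [tile_bins()] tiling.
#' @param classes Mutation classes to tabulate (default all 12).
#' @return A `data.frame` (class `binned_freq`) with columns `class`, `bin`,
#'   `start`, `end`, `mutation_count`, `mutable_depth`, `frequency`.
#' @export
binned_frequency <- function(records, depths, genome, bins,
                             classes = mutation_classes()) {
  if (depths$genome_length != genome$length) {
    stop("depth profile length does not match the genome")
  }
  if (!"class" %in% names(records)) records <- classify_records(records)
  ch <- genome_bases(genome)
  nb <- nrow(bins)
  if (nrow(records)) {
    pos <- as.integer(records$position)
    if (any(pos < 1L) || any(pos > genome$length)) {
      stop("record position outside the genome")
    }
    sidx <- match(records$sample_id, depths$sample_ids)
    if (any(is.na(sidx))) {
      stop("record sample(s) missing from the depth profile: ",
           paste(unique(records$sample_id[is.na(sidx)]), collapse = ", "))
    }
    wt <- substr(records$class, 1L, 1L)
    mism <- ch[pos] != wt
    if (any(mism)) {
      i <- which(mism)[1L]
      stop("record wild-type base disagrees with the reference at position ",
           pos[i], " (sample ", records$sample_id[i], ")")
    }
    d <- depths$depth[cbind(pos, sidx)]
    if (any(d <= 0)) {
      i <- which(d <= 0)[1L]
      stop("mutation at position ", pos[i], " of sample ",
           records$sample_id[i], " has zero reported wild-type depth")
    }
  }
  td <- rowSums(depths$depth)
  out <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    rb <- substr(cl, 1L, 1L)
    sel <- which(ch == rb)
    S <- .bin_sum(td[sel], sel, bins)
    M <- numeric(nb)
    if (nrow(records)) {
      rp <- records$position[records$class == cl]
      if (length(rp)) M <- tabulate(bin_of(rp, bins), nbins = nb)
    }
    out[[k]] <- data.frame(class = cl, bin = bins$index, start = bins$start,
                           end = bins$end, mutation_count = M,
                           mutable_depth = S,
                           frequency = ifelse(S > 0, M / S, NA_real_))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "bins") <- bins
  class(tab) <- c("binned_freq", "data.frame")
  tab
}

#' Leave-one-group-out binned frequencies
#'
#' Recomputes [binned_frequency()] with one group (e.g. one tissue) held out
#' at a time, removing both the group's mutation records and its samples'
#' depth columns. Used to check that no single group drives a gradient.
#'
#' @param records,depths,genome,bins,classes As in [binned_frequency()].
#' @param group_field Column of `records` defining the groups.
#' @param sample_groups Optional named vector mapping sample id to group;
#'   derived from `records` when absent (samples never seen in `records`
#'   then stay in every reduced set).
#' @return Named list of `binned_freq` tables, one per held-out group.
#' @export
leave_one_out <- function(records, depths, genome, bins,
                          group_field = "tissue",
                          classes = mutation_classes(),
                          sample_groups = NULL) {
  if (!group_field %in% names(records)) {
    stop("records have no column '", group_field, "'")
  }
  grp <- as.character(records[[group_field]])
  groups <- unique(grp)
  if (length(groups) < 2L) stop("need at least 2 distinct groups")
  if (is.null(sample_groups)) {
    sample_groups <- tapply(grp, records$sample_id, function(g) g[1L])
  }
  out <- lapply(groups, function(g) {
    rec <- records[grp != g, , drop = FALSE]
    drop_samples <- names(sample_groups)[sample_groups == g]
    keep <- setdiff(depths$sample_ids, drop_samples)
    binned_frequency(rec, subset_samples(depths, keep), genome, bins, classes)
  })
  names(out) <- groups
  out
}

#' Cohort-level mutation count summary
#'
#' Totals, per-group counts, mean mutations per sample and the mean
#' per-sample mutation density (mean count divided by genome length).
#'
#' @param records Variant `data.frame` with `sample_id` and the grouping
#'   column.
#' @param genome_length Genome length in bp.
#' @param group_field Grouping column, default `"age_group"`.
#' @return A list: `groups` (`data.frame` of per-group `n_mutations`,
#'   `n_samples`, `mean_per_sample`), `total_mutations`, `n_samples`,
#'   `mean_per_sample`, `density_per_bp`.
#' @export
mutation_summary <- function(records, genome_length,
                             group_field = "age_group") {
  grp <- if (group_field %in% names(records)) {
    as.character(records[[group_field]])
  } else {
    rep("all", nrow(records))
  }
  gtab <- do.call(rbind, lapply(unique(grp), function(g) {
    r <- records[grp == g, , drop = FALSE]
    ns <- length(unique(r$sample_id))
    data.frame(group = g, n_mutations = nrow(r), n_samples = ns,
               mean_per_sample = nrow(r) / ns)
  }))
  ns <- length(unique(records$sample_id))
  mean_ps <- nrow(records) / ns
  list(groups = gtab, total_mutations = nrow(records), n_samples = ns,
       mean_per_sample = mean_ps,
       density_per_bp = mean_ps / genome_length)
}
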