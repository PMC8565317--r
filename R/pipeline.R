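# Orchestration: configuration objects and the two report-producing drivers
# that chain the stages (frequency -> regression -> permutation, and the
# rotated-frame control-region scan).

#' Analysis configuration
#'
#' Collects the tunables of a full analysis run and validates them once.
#' Serializable to JSON with [write_analysis_config()] so that every
#' report can echo the exact configuration that produced it.
#'
#' @param genome_length Genome length in bp.
#' @param bin_size Somatic-analysis bin size (default 100).
#' @param mcr_bin_size Control-region scan bin size (default 50).
#' @param snp_bin_size SNP-density bin size (default 200).
#' @param arcs An [arc_definitions()] object.
#' @param mcr_window Length-2 control-region scan window (positions).
#' @param vaf_max VAF cutoff (exclusive).
#' @param n_perm Gradient permutation count (default 10,000).
#' @param n_perm_mcr Control-region scan permutation count (default
#'   100,000).
#' @param family_alpha Family-wise level of the scan envelope.
#' @param seed RNG seed.
#' @return Object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(genome_length = 16299, bin_size = 100,
                            mcr_bin_size = 50, snp_bin_size = 200,
                            arcs = mouse_mt_arcs(),
                            mcr_window = c(15300, 16299),
                            vaf_max = 0.01, n_perm = 10000,
                            n_perm_mcr = 100000, family_alpha = 0.05,
                            seed = 1) {
  stopifnot(genome_length >= 1, bin_size >= 1, mcr_bin_size >= 1,
            snp_bin_size >= 1, vaf_max > 0, vaf_max <= 1, n_perm >= 1,
            n_perm_mcr >= 1, family_alpha > 0, family_alpha < 1)
  structure(list(genome_length = as.numeric(genome_length),
                 bin_size = as.numeric(bin_size),
                 mcr_bin_size = as.numeric(mcr_bin_size),
                 snp_bin_size = as.numeric(snp_bin_size),
                 arcs = data.frame(name = arcs$name,
                                   bin_start = as.numeric(arcs$bin_start),
                                   bin_end = as.numeric(arcs$bin_end)),
                 mcr_window = as.numeric(mcr_window),
                 vaf_max = as.numeric(vaf_max),
                 n_perm = as.numeric(n_perm),
                 n_perm_mcr = as.numeric(n_perm_mcr),
                 family_alpha = as.numeric(family_alpha),
                 seed = as.numeric(seed)),
            class = "analysis_config")
}

#' Write / read an analysis configuration as JSON
#' @param config An [analysis_config()].
#' @param path File path.
#' @return `read_analysis_config` returns the restored `analysis_config`;
#'   the round trip `read(write(config))` reproduces the input.
#' @export
write_analysis_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- as.data.frame(x$arcs)
  pick <- function(nm) {
    if (!nm %in% a$name) return(NULL)
    i <- match(nm, a$name)
    c(a$bin_start[i], a$bin_end[i])
  }
  arcs <- arc_definitions(minor = pick("minor"), major = pick("major"),
                          mcr = pick("mcr"))
  analysis_config(genome_length = x$genome_length, bin_size = x$bin_size,
                  mcr_bin_size = x$mcr_bin_size,
                  snp_bin_size = x$snp_bin_size, arcs = arcs,
                  mcr_window = x$mcr_window, vaf_max = x$vaf_max,
                  n_perm = x$n_perm, n_perm_mcr = x$n_perm_mcr,
                  family_alpha = x$family_alpha, seed = x$seed)
}

# sample -> group map derived from records unless supplied
.sample_map <- function(records, field, override = NULL) {
  if (!is.null(override)) return(override)
  tapply(as.character(records[[field]]), records$sample_id,
         function(g) g[1L])
}

#' Full somatic gradient analysis
#'
#' Chains the pipeline stages on one dataset: VAF filter, classification,
#' binned frequency, robust minor/major-arc gradient fits per class,
#' composition-aware permutation p-values over the coding (non-mCR)
#' interval, the age-by-position interaction model when both cohorts are
#' present, and an optional leave-one-group-out section. Identical inputs
#' and seed reproduce the report bit-for-bit.
#'
#' @param records Variant `data.frame` (`sample_id`, `position`, `ref`,
#'   `alt`, `vaf`, optionally `tissue`, `age_group`).
#' @param depths A [depth_profile()].
#' @param genome A [circular_genome()] with sequence.
#' @param bin_size Bin width (default 100).
#' @param arcs Arc layout (default [mouse_mt_arcs()]).
#' @param classes Classes to analyze (default all 12).
#' @param vaf_max VAF cutoff (exclusive, default 0.01).
#' @param n_perm Permutation replicates per class and arc; 0 skips the
#'   permutation stage.
#' @param seed RNG seed for the permutation stage.
#' @param estimator Regression estimator (default `"huber"`).
#' @param coding_bins Bins forming the permutation interval; default all
#'   bins before the mCR arc (bins 1-153 on the mouse layout).
#' @param age_field,interaction Age-grouping column and whether to fit the
#'   interaction model when exactly two groups are present.
#' @param leave_one_out_field Optional grouping column for the
#'   leave-one-out section (e.g. `"tissue"`).
#' @param sample_ages Optional named sample-to-age map (derived from
#'   `records` when absent).
#' @return Object of class `gradient_report` (nested lists; see elements
#'   `table`, `fits`, `permutation`, `interaction`, `leave_one_out`,
#'   `counts`, `config`).
#' @export
run_somatic_gradient <- function(records, depths, genome, bin_size = 100,
                                 arcs = mouse_mt_arcs(),
                                 classes = mutation_classes(),
                                 vaf_max = 0.01, n_perm = 10000,
                                 seed = NULL, estimator = "huber",
                                 coding_bins = NULL,
                                 age_field = "age_group",
                                 interaction = TRUE,
                                 leave_one_out_field = NULL,
                                 sample_ages = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bins <- tile_bins(genome$length, bin_size)
  if (is.null(coding_bins)) {
    coding_bins <- if ("mcr" %in% arcs$name) {
      seq_len(arcs$bin_start[arcs$name == "mcr"] - 1L)
    } else {
      bins$index
    }
  }
  n_input <- nrow(records)
  flt <- filter_by_vaf(records, vaf_max)
  rec <- flt$records
  n_ambiguous <- 0L
  if (!"class" %in% names(rec)) {
    rec <- classify_records(rec)
    n_ambiguous <- attr(rec, "n_ambiguous")
  }
  tab <- binned_frequency(rec, depths, genome, bins, classes)
  arc_names <- intersect(c("minor", "major"), arcs$name)
  per_class <- lapply(classes, function(cl) {
    ctab <- tab[tab$class == cl, , drop = FALSE]
    fits <- list(); perms <- list()
    n_coding <- sum(ctab$mutation_count[ctab$bin %in% coding_bins])
    S_coding <- ctab$mutable_depth[match(coding_bins, ctab$bin)]
    for (an in arc_names) {
      ab <- arc_bin_range(arcs, an)
      fits[[an]] <- tryCatch(
        fit_arc_gradient(ctab, ab, estimator = estimator, arc = an),
        error = function(e) e$message
      )
      if (n_perm >= 1 && n_coding >= 1 && inherits(fits[[an]], "arc_fit")) {
        perms[[an]] <- tryCatch(
          gradient_permutation_test(
            n_mutations = n_coding,
            weights = compute_bin_weights(S_coding, coding_bins),
            bin_depths = S_coding, arc_bins = ab,
            observed_slope = fits[[an]]$slope, n_perm = n_perm,
            estimator = estimator
          ),
          error = function(e) e$message
        )
      }
    }
    list(class = cl, n_mutations = sum(ctab$mutation_count),
         n_coding = n_coding, fits = fits, permutation = perms)
  })
  names(per_class) <- classes
  # age interaction
  inter <- NULL
  tabs_by_age <- NULL
  if (interaction && age_field %in% names(rec) && nrow(rec)) {
    age_map <- .sample_map(rec, age_field, sample_ages)
    age_levels <- unique(as.character(rec[[age_field]]))
    if (length(age_levels) == 2L) {
      ord <- if (all(c("young", "old") %in% age_levels)) {
        c("young", "old")
      } else {
        sort(age_levels)
      }
      tabs_by_age <- lapply(ord, function(a) {
        keep <- intersect(depths$sample_ids,
                          names(age_map)[age_map == a])
        binned_frequency(rec[rec[[age_field]] == a, , drop = FALSE],
                         subset_samples(depths, keep), genome, bins,
                         classes)
      })
      names(tabs_by_age) <- ord
      inter <- lapply(classes, function(cl) {
        out <- list()
        for (an in arc_names) {
          out[[an]] <- tryCatch(
            fit_age_interaction(tabs_by_age[[1]], tabs_by_age[[2]],
                                arc_bin_range(arcs, an),
                                estimator = estimator, class = cl),
            error = function(e) e$message
          )
        }
        out
      })
      names(inter) <- classes
    }
  }
  loo <- NULL
  if (!is.null(leave_one_out_field) &&
      leave_one_out_field %in% names(rec)) {
    loo_tabs <- leave_one_out(rec, depths, genome, bins,
                              group_field = leave_one_out_field,
                              classes = classes)
    loo <- lapply(loo_tabs, function(t1) {
      lapply(stats::setNames(classes, classes), function(cl) {
        out <- list()
        for (an in arc_names) {
          out[[an]] <- tryCatch(
            fit_arc_gradient(t1, arc_bin_range(arcs, an),
                             estimator = estimator, class = cl, arc = an),
            error = function(e) e$message
          )
        }
        out
      })
    })
  }
  structure(list(
    table = tab, classes = per_class, interaction = inter,
    tables_by_age = tabs_by_age, leave_one_out = loo,
    counts = list(n_input = n_input, n_vaf_rejected = flt$n_rejected,
                  n_ambiguous = n_ambiguous, n_kept = nrow(rec)),
    config = list(bin_size = bin_size, arcs = arcs, classes = classes,
                  vaf_max = vaf_max, n_perm = n_perm, seed = seed,
                  estimator = estimator, coding_bins = range(coding_bins)),
    version = as.character(utils::packageVersion("mitogradient"))
  ), class = "gradient_report")
}

#' Control-region hot/cold-spot report
#'
#' Bins the scan window (50-bp bins by default, 20 of them on the default
#' mouse window) and runs [mcr_hotspot_scan()] per transition class. The
#' window may wrap through the sequence origin; on references where the
#' control region abuts the end, analyze either frame — the scan depends
#' only on positions, which [rotate_reference()] maps bijectively.
#'
#' @param records,depths,genome As in [run_somatic_gradient()].
#' @param window Length-2 position window (default the 1,000-bp mouse
#'   control-region window 15,300-16,299).
#' @param bin_size Scan bin width (default 50).
#' @param classes Classes to scan (default the four transitions).
#' @param n_perm Monte-Carlo replicates (default 100,000).
#' @param family_alpha Family-wise envelope level (default 0.05).
#' @param vaf_max VAF cutoff.
#' @param seed RNG seed.
#' @return Object of class `mcr_report`: per-class `hotspot_scan` tables
#'   plus the window geometry and envelope arithmetic (`K`,
#'   `per_bin_alpha`, `envelope_level`).
#' @export
run_mcr_scan <- function(records, depths, genome, window = c(15300, 16299),
                         bin_size = 50,
                         classes = c("C>T", "G>A", "T>C", "A>G"),
                         n_perm = 100000, family_alpha = 0.05,
                         vaf_max = 0.01, seed = NULL) {
  if (nrow(records) == 0L) stop("insufficient data: empty variant set")
  L <- genome$length
  W <- if (window[2] >= window[1]) {
    window[2] - window[1] + 1
  } else {
    (L - window[1] + 1) + window[2]
  }
  if (W < bin_size) stop("invalid config: window shorter than one bin")
  if (!is.null(seed)) set.seed(seed)
  flt <- filter_by_vaf(records, vaf_max)
  rec <- flt$records
  if (!"class" %in% names(rec)) rec <- classify_records(rec)
  K <- as.integer(ceiling(W / bin_size))
  gp <- (((window[1] - 1) + seq_len(W) - 1) %% L) + 1  # genome positions
  wbin <- pmin(ceiling(seq_len(W) / bin_size), K)
  ch <- genome_bases(genome)[gp]
  td <- rowSums(depths$depth)[gp]
  roff <- match(rec$position, gp)  # NA for records outside the window
  scans <- list()
  for (cl in classes) {
    rb <- substr(cl, 1L, 1L)
    S <- vapply(seq_len(K), function(k) {
      sum(td[wbin == k & ch == rb])
    }, numeric(1))
    inwin <- !is.na(roff) & rec$class == cl
    obs <- tabulate(wbin[roff[inwin]], nbins = K)
    scans[[cl]] <- if (sum(obs) >= 1) {
      mcr_hotspot_scan(obs, S, n_perm = n_perm,
                       family_alpha = family_alpha)
    } else {
      "insufficient data: no mutations of this class in the window"
    }
  }
  structure(list(scans = scans, window = window, bin_size = bin_size,
                 K = K, per_bin_alpha = family_alpha / K,
                 envelope_level = 1 - family_alpha / K,
                 counts = list(n_input = nrow(records),
                               n_vaf_rejected = flt$n_rejected),
                 config = list(n_perm = n_perm,
                               family_alpha = family_alpha,
                               vaf_max = vaf_max, seed = seed),
                 version = as.character(
                   utils::packageVersion("mitogradient"))),
            class = "mcr_report")
}
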