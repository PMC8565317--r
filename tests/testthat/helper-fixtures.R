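# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

toy_genome <- function(seqstr, name = "toy") {
  circular_genome(name, sequence = seqstr)
}

# genome whose every position carries the same base
mono_genome <- function(base, length) {
  toy_genome(paste(rep(base, length), collapse = ""))
}

rand_genome <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  toy_genome(random_mt_sequence(length))
}

const_depths <- function(genome_length, sample_ids, depth) {
  depth_profile(matrix(depth, nrow = genome_length,
                       ncol = length(sample_ids)),
                sample_ids)
}

# variant records of a given class at given positions (ref taken from the
# class label; caller must place them on matching reference bases)
records_of <- function(sample_id, position, class, vaf = 1e-3,
                       tissue = "t1", age_group = "young") {
  n <- max(length(sample_id), length(position))
  data.frame(sample_id = rep_len(sample_id, n),
             position = rep_len(as.integer(position), n),
             ref = substr(rep_len(class, n), 1, 1),
             alt = substr(rep_len(class, n), 3, 3),
             vaf = rep_len(vaf, n),
             tissue = rep_len(tissue, n),
             age_group = rep_len(age_group, n),
             class = rep_len(class, n),
             stringsAsFactors = FALSE)
}

positions_of <- function(genome, base, n = Inf) {
  p <- which(strsplit(genome$sequence, "")[[1]] == base)
  if (is.finite(n)) p <- head(p, n)
  p
}

# small single-class, single-group simulation configuration
quick_config <- function(classes = "G>A", slope = 8e-8, baseline = 1.6e-6,
                         n_samples = 10L, depth = 1e4) {
  b <- default_base_rates()
  g <- default_gradient_slopes()
  b[] <- baseline
  g[] <- 0
  g[classes[1]] <- slope
  simulation_config(base_rates = b, gradient_slopes = g,
                    age_multipliers = c(adult = 1),
                    n_samples = c(adult = n_samples),
                    mean_depth = depth, classes = classes)
}
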