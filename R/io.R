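# I/O boundary. Tidy TSV is the native interchange format; FASTA and VCF
# readers use Biostrings / vcfR when available. This is the only layer that
# converts between 1-based inclusive coordinates (used everywhere inside)
# and 0-based half-open ones (BED).

.std_names <- c(sample = "sample_id", sample_id = "sample_id",
                position = "position", pos = "position", ref = "ref",
                alt = "alt", vaf = "vaf", tissue = "tissue",
                age = "age_group", age_group = "age_group",
                strand = "strand", frequency = "frequency",
                freq = "frequency", count = "n_observed", depth = "depth",
                base = "base")

.standardize <- function(df) {
  hit <- names(df) %in% names(.std_names)
  names(df)[hit] <- unname(.std_names[names(df)[hit]])
  df
}

#' Read a reference genome from FASTA
#' @param path FASTA file (first record used).
#' @param name Genome name (default the FASTA header).
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path, name = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequence in ", path)
  if (is.null(name)) name <- names(ss)[1]
  circular_genome(name, sequence = as.character(ss[[1]]))
}

#' Read a variant table from TSV
#'
#' Expects a header with at least `sample` (or `sample_id`), `position`,
#' `ref`, `alt`, `vaf`; `tissue`, `age` (or `age_group`) and `strand` are
#' carried through when present. Multi-allelic `alt` entries
#' (comma-separated) are split into one record per alternate allele before
#' classification.
#'
#' @param path TSV file.
#' @return A variant `data.frame` with standardized column names.
#' @export
read_variants_tsv <- function(path) {
  df <- .standardize(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  req <- c("sample_id", "position", "ref", "alt", "vaf")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("variant TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(grepl(",", df$alt, fixed = TRUE))) {
    alts <- strsplit(df$alt, ",", fixed = TRUE)
    df <- df[rep(seq_len(nrow(df)), lengths(alts)), , drop = FALSE]
    df$alt <- unlist(alts)
    rownames(df) <- NULL
  }
  df$position <- as.integer(df$position)
  df
}

#' Read a variant table from VCF
#'
#' One sample per file; the VAF is taken from the named INFO field. Multi-
#' allelic sites are split into one record per alternate allele.
#'
#' @param path VCF file.
#' @param sample_id Sample label to assign.
#' @param af_field INFO field carrying the variant allele fraction.
#' @return A variant `data.frame`.
#' @export
read_variants_vcf <- function(path, sample_id, af_field = "AF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- vcfR::extract.info(v, element = af_field)
  df <- data.frame(sample_id = sample_id,
                   position = as.integer(fix$POS), ref = fix$REF,
                   alt = fix$ALT, vaf_raw = af,
                   stringsAsFactors = FALSE)
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  afs <- strsplit(df$vaf_raw, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- df[rep(seq_len(nrow(df)), n), c("sample_id", "position", "ref")]
  out$alt <- unlist(alts)
  out$vaf <- as.numeric(unlist(mapply(function(a, f) rep_len(f, length(a)),
                                      alts, afs, SIMPLIFY = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read a per-base depth table from TSV
#'
#' Long format with header `sample`, `position`, `depth` (a `base` column,
#' if present, is ignored for the matrix — the reference base at each
#' position comes from the genome sequence). Missing (sample, position)
#' pairs get depth 0.
#'
#' @param path TSV file.
#' @param genome_length Genome length (rows of the resulting matrix).
#' @return A [depth_profile()].
#' @export
read_depth_tsv <- function(path, genome_length) {
  df <- .standardize(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  req <- c("sample_id", "position", "depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("depth TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  ids <- unique(df$sample_id)
  m <- matrix(0, nrow = genome_length, ncol = length(ids),
              dimnames = list(NULL, ids))
  # sum duplicates (e.g. per-base rows at one position)
  idx <- cbind(as.integer(df$position), match(df$sample_id, ids))
  for (r in seq_len(nrow(df))) {
    m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + df$depth[r]
  }
  depth_profile(m, ids)
}

#' Read a SNP list from TSV
#'
#' Header `position`, `ref`, `alt`, optionally `frequency` (population
#' frequency) and `count` (occurrences).
#'
#' @param path TSV file.
#' @return A SNP `data.frame` for [preprocess_snps()].
#' @export
read_snps_tsv <- function(path) {
  df <- .standardize(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  req <- c("position", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("SNP TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df
}

#' Read annotation intervals (TSV or BED)
#'
#' TSV: header `label`, `start`, `end`, 1-based inclusive. BED: 3+ columns,
#' 0-based half-open, converted on read.
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return `data.frame` with `label`, `start`, `end` (1-based inclusive).
#' @export
read_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    data.frame(label = df$label, start = as.integer(df$start),
               end = as.integer(df$end))
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    data.frame(label = if (ncol(df) >= 4) df[[4]] else
                 paste0("feature", seq_len(nrow(df))),
               start = as.integer(df[[2]]) + 1L,
               end = as.integer(df[[3]]))
  }
}

#' Write a tidy per-bin table to TSV
#' @param table A `binned_freq`, `density_table`, or `hotspot_scan`.
#' @param path Output file.
#' @export
write_bin_table_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# recursively strip closures/envs so reports serialize cleanly
.json_clean <- function(x) {
  if (is.function(x) || is.environment(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, .json_clean)
    return(x[!vapply(x, is.null, logical(1))])
  }
  x
}

#' Serialize fit / permutation / report objects to JSON
#' @param x A report or result object.
#' @param path Output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(.json_clean(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
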