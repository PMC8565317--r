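# Circular-genome coordinate system: binning, rotation, arc assignment.
# All coordinates are 1-based inclusive; converters to/from 0-based
# half-open formats (BED) live in the I/O layer only.

BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Circular genome object
#'
#' A minimal container for a circular (mitochondrial) genome: a name, its
#' length, optionally its reference (light-strand) sequence, and optional
#' feature annotations. Annotation coordinates are normalized into
#' `[1, length]` circularly.
#'
#' @param name Genome name (e.g. `"chrM"`).
#' @param length Genome length in bp. May be omitted when `sequence` is given.
#' @param sequence Optional reference-strand sequence (single string).
#' @param annotations Optional `data.frame` with columns `label`, `start`,
#'   `end` (1-based inclusive, reference strand).
#' @return An object of class `circular_genome`.
#' @export
circular_genome <- function(name, length = NULL, sequence = NULL,
                            annotations = NULL) {
  if (is.null(length) && is.null(sequence)) {
    stop("either `length` or `sequence` must be supplied")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != 1L) stop("`sequence` must be a single string")
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length) {
      stop("sequence length (", nchar(sequence),
           ") does not equal `length` (", length, ")")
    }
  }
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("genome length must be >= 1")
  if (!is.null(annotations)) {
    req <- c("label", "start", "end")
    if (!all(req %in% names(annotations))) {
      stop("annotations need columns label, start, end")
    }
    annotations$start <- ((as.integer(annotations$start) - 1L) %% length) + 1L
    annotations$end <- ((as.integer(annotations$end) - 1L) %% length) + 1L
  }
  structure(list(name = name, length = length, sequence = sequence,
                 annotations = annotations),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome>", x$name, "-", x$length, "bp",
      if (is.null(x$sequence)) "(no sequence)" else "(with sequence)", "\n")
  invisible(x)
}

# character vector of reference bases, one per position
genome_bases <- function(genome) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  strsplit(genome$sequence, "", fixed = TRUE)[[1]]
}

#' Tile a circular genome into fixed-width bins
#'
#' Bins of `bin_size` bp tile the genome starting at `origin`; the final bin
#' keeps the remainder width (it is never merged), so the bin count is
#' `ceiling(genome_length / bin_size)`. For the 16,299-bp mouse mitochondrial
#' genome at 100 bp this yields 163 bins, the last one 99 bp wide.
#'
#' @param genome_length Genome length in bp.
#' @param bin_size Bin width in bp; must be in `[1, genome_length]`.
#' @param origin 1-based position at which bin 1 starts.
#' @return A `data.frame` (class `genome_bins`) with columns `index`,
#'   `start`, `end`, `width`; attributes `bin_size`, `genome_length`,
#'   `origin`. `start`/`end` are expressed on the unrolled axis beginning at
#'   `origin`; use [bin_of()] to map genome positions to bins.
#' @export
tile_bins <- function(genome_length, bin_size, origin = 1L) {
  genome_length <- as.integer(genome_length)
  bin_size <- as.integer(bin_size)
  origin <- as.integer(origin)
  if (is.na(bin_size) || bin_size < 1L || bin_size > genome_length) {
    stop("`bin_size` must be between 1 and the genome length")
  }
  if (is.na(origin) || origin < 1L || origin > genome_length) {
    stop("`origin` must be a position within the genome")
  }
  n <- as.integer(ceiling(genome_length / bin_size))
  start <- origin + (seq_len(n) - 1L) * bin_size
  end <- pmin(start + bin_size - 1L, origin + genome_length - 1L)
  bins <- data.frame(index = seq_len(n), start = start, end = end,
                     width = end - start + 1L)
  attr(bins, "bin_size") <- bin_size
  attr(bins, "genome_length") <- genome_length
  attr(bins, "origin") <- origin
  class(bins) <- c("genome_bins", "data.frame")
  bins
}

#' Map genome positions to bin indices
#'
#' @param position Integer vector of 1-based genome positions.
#' @param bins A tiling from [tile_bins()].
#' @return Integer vector of bin indices.
#' @export
bin_of <- function(position, bins) {
  L <- attr(bins, "genome_length")
  b <- attr(bins, "bin_size")
  o <- attr(bins, "origin")
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > L)) {
    stop("positions must lie in [1, ", L, "]")
  }
  off <- ((position - o) %% L) + 1L
  pmin(as.integer(ceiling(off / b)), nrow(bins))
}

#' Rotate a circular reference
#'
#' Cuts the circle after `cut_after` so that position `cut_after + 1` becomes
#' position 1 of the rotated reference. Used to move the control region away
#' from the linearized ends (the alignment-bias workaround for references
#' whose control region abuts the sequence terminus). Returns the rotated
#' genome together with the coordinate bijection in both directions.
#'
#' @param genome A [circular_genome()].
#' @param cut_after Position after which the circle is cut (1..length).
#' @return A list with elements `genome` (rotated `circular_genome`),
#'   `to_rotated` and `to_original` (vectorized position maps, mutual
#'   inverses), and `cut_after`.
#' @export
rotate_reference <- function(genome, cut_after) {
  L <- genome$length
  cut_after <- as.integer(cut_after)
  if (is.na(cut_after) || cut_after < 1L || cut_after > L) {
    stop("`cut_after` must lie in [1, ", L, "]")
  }
  to_rotated <- function(pos) ((as.integer(pos) - cut_after - 1L) %% L) + 1L
  to_original <- function(pos) ((as.integer(pos) + cut_after - 1L) %% L) + 1L
  rotseq <- NULL
  if (!is.null(genome$sequence) && cut_after < L) {
    rotseq <- paste0(substr(genome$sequence, cut_after + 1L, L),
                     substr(genome$sequence, 1L, cut_after))
  } else {
    rotseq <- genome$sequence
  }
  ann <- genome$annotations
  if (!is.null(ann)) {
    ann$start <- to_rotated(ann$start)
    ann$end <- to_rotated(ann$end)
  }
  rot <- circular_genome(paste0(genome$name, "_rot", cut_after), L,
                         sequence = rotseq, annotations = ann)
  list(genome = rot, to_rotated = to_rotated, to_original = to_original,
       cut_after = cut_after)
}

#' Extract a (possibly wrapping) window from a circular sequence
#'
#' When `end < start` the window wraps through the origin, e.g. positions
#' 14,400..16,299 followed by 1..1,001 of a 16,299-bp genome give a single
#' 2,901-bp string.
#'
#' @param genome A [circular_genome()] carrying a sequence, or a string.
#' @param start,end 1-based inclusive window bounds.
#' @return The window sequence as a single string.
#' @export
extract_circular <- function(genome, start, end) {
  seqstr <- if (inherits(genome, "circular_genome")) {
    if (is.null(genome$sequence)) stop("genome has no sequence")
    genome$sequence
  } else {
    as.character(genome)
  }
  L <- nchar(seqstr)
  start <- as.integer(start); end <- as.integer(end)
  if (any(c(start, end) < 1L) || any(c(start, end) > L)) {
    stop("window bounds must lie in [1, ", L, "]")
  }
  if (end >= start) {
    substr(seqstr, start, end)
  } else {
    paste0(substr(seqstr, start, L), substr(seqstr, 1L, end))
  }
}

#' Arc definitions on a binned genome
#'
#' The replication arcs are delimited by the light-strand origin and the
#' control region (mCR): the minor arc runs from the end of the mCR to
#' Ori_L, the major arc from Ori_L to the start of the mCR. Defaults are the
#' mouse coordinates at 100-bp binning (minor: bins 1-47, positions 1-4,800;
#' major: bins 53-153, positions 5,300-15,400; mCR: bins 154-163). Bins
#' covered by no arc (the Ori_L gap, bins 48-52) are "excluded".
#'
#' @param minor,major,mcr Length-2 integer vectors of inclusive bin ranges,
#'   or `NULL` to omit the arc.
#' @return A `data.frame` (class `arc_definitions`) with columns `name`,
#'   `bin_start`, `bin_end`.
#' @export
arc_definitions <- function(minor = c(1L, 47L), major = c(53L, 153L),
                            mcr = c(154L, 163L)) {
  parts <- list(minor = minor, major = major, mcr = mcr)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  df <- data.frame(
    name = names(parts),
    bin_start = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    bin_end = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    row.names = NULL
  )
  if (any(df$bin_end < df$bin_start)) stop("arc bin ranges must be ordered")
  # pairwise disjoint
  covered <- unlist(mapply(seq, df$bin_start, df$bin_end, SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) stop("arc bin ranges must be pairwise disjoint")
  class(df) <- c("arc_definitions", "data.frame")
  df
}

#' Default mouse mitochondrial arc layout (100-bp bins)
#' @return An [arc_definitions()] object.
#' @export
mouse_mt_arcs <- function() arc_definitions()

#' Default analysis constants for the mouse mitochondrial genome
#'
#' @return A list: `genome_length` (16,299), `bin_size` (100), `arcs`
#'   ([mouse_mt_arcs()]), `mcr_window` (the 20 x 50-bp control-region scan
#'   window, positions 15,300-16,299), `coding_bins` (bins 1-153, the
#'   non-mCR interval used for the gradient permutation test).
#' @export
mouse_mt_defaults <- function() {
  list(genome_length = 16299L, bin_size = 100L, arcs = mouse_mt_arcs(),
       mcr_window = c(15300L, 16299L), coding_bins = 1:153)
}

#' Bin range of a named arc
#' @param arcs An [arc_definitions()] object.
#' @param name Arc name (`"minor"`, `"major"`, `"mcr"`).
#' @return Integer vector of bin indices.
#' @export
arc_bin_range <- function(arcs, name) {
  i <- match(name, arcs$name)
  if (is.na(i)) stop("no arc named '", name, "'")
  seq.int(arcs$bin_start[i], arcs$bin_end[i])
}

#' Assign bins to arcs
#'
#' Total, deterministic lookup: a bin covered by no defined arc maps to
#' `"excluded"` (e.g. the Ori_L gap bins between the arcs).
#'
#' @param bin_index Integer vector of bin indices.
#' @param arcs An [arc_definitions()] object.
#' @return Character vector of arc names.
#' @export
assign_arc <- function(bin_index, arcs) {
  out <- rep("excluded", length(bin_index))
  for (i in seq_len(nrow(arcs))) {
    hit <- bin_index >= arcs$bin_start[i] & bin_index <= arcs$bin_end[i]
    out[hit] <- arcs$name[i]
  }
  out
}
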