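# Mutation-class taxonomy with strand-complement equivalence.
# Class labels are always expressed on the reference (L) strand as "X>Y".

#' The 12 single-nucleotide mutation classes
#'
#' All ordered pairs of distinct bases, labeled `"X>Y"` on the reference
#' (light) strand: `"A>C"`, `"A>G"`, ..., `"T>G"`.
#'
#' @return Character vector of length 12.
#' @export
mutation_classes <- function() {
  unlist(lapply(BASES, function(r) paste0(r, ">", setdiff(BASES, r))),
         use.names = FALSE)
}

#' Classify a substitution onto the reference (L) strand
#'
#' Calls reported on the heavy (H) strand are complemented onto the
#' light-strand frame before labeling, so an H-strand C>T is the class
#' `"G>A"`. Ambiguous bases yield `NA` (the caller counts and drops them);
#' a ref equal to alt is an error.
#'
#' @param ref_base,alt_base Base characters (vectorized).
#' @param strand `"L"` or `"H"` (recycled).
#' @return Character vector of class labels, `NA` where a base is not one of
#'   A/C/G/T.
#' @export
classify_mutation <- function(ref_base, alt_base, strand = "L") {
  n <- max(length(ref_base), length(alt_base))
  ref <- toupper(rep_len(as.character(ref_base), n))
  alt <- toupper(rep_len(as.character(alt_base), n))
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("L", "H"))) stop("strand must be 'L' or 'H'")
  h <- strand == "H"
  ref[h] <- unname(BASE_COMPLEMENT[ref[h]])
  alt[h] <- unname(BASE_COMPLEMENT[alt[h]])
  ok <- !is.na(ref) & !is.na(alt) & ref %in% BASES & alt %in% BASES
  if (any(ref[ok] == alt[ok])) {
    stop("ref and alt base are identical after strand resolution")
  }
  out <- rep(NA_character_, n)
  out[ok] <- paste0(ref[ok], ">", alt[ok])
  out
}

#' Complementary mutation class
#'
#' Maps a class to its strand complement, e.g. `complement_class("G>A")`
#' is `"C>T"`. The mapping is an involution over the 12 classes.
#'
#' @param class Character vector of `"X>Y"` labels.
#' @return Character vector of complementary labels.
#' @export
complement_class <- function(class) {
  ref <- substr(class, 1L, 1L)
  alt <- substr(class, 3L, 3L)
  paste0(unname(BASE_COMPLEMENT[ref]), ">", unname(BASE_COMPLEMENT[alt]))
}

#' Attach class labels to a variant table
#'
#' Adds a `class` column via [classify_mutation()]. Records with ambiguous
#' bases are dropped with a warning; the number dropped is recorded in the
#' `n_ambiguous` attribute of the result.
#'
#' @param records `data.frame` with columns `ref`, `alt` and optionally
#'   `strand` (`"L"`/`"H"`; absent means `"L"`).
#' @return The records with a `class` column.
#' @export
classify_records <- function(records) {
  strand <- if ("strand" %in% names(records)) records$strand else "L"
  cls <- classify_mutation(records$ref, records$alt, strand)
  bad <- is.na(cls)
  if (any(bad)) {
    warning("dropped ", sum(bad), " record(s) with ambiguous bases")
  }
  out <- records[!bad, , drop = FALSE]
  out$class <- cls[!bad]
  attr(out, "n_ambiguous") <- sum(bad)
  out
}
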