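# Variant identity and the core containers.
#
# A variant is identified by exact match on (chrom, pos, ref, alt).  Internally
# variants live in a "variant table": a data.frame with columns chrom
# (character, verbatim), pos (integer, 1-based), ref, alt (uppercase character)
# and key, a tab-joined encoding of the four fields.  Tab is safe as a
# separator because the source format is tab-delimited, so no field can
# contain one.

#' Build a variant table
#'
#' Constructs the canonical variant table from parallel vectors of the four
#' identity components. REF and ALT are uppercased; chromosome names are kept
#' verbatim (no `"chr1"`/`"1"` normalization). Duplicate
#' (chrom, pos, ref, alt) rows are collapsed, keeping the first occurrence.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (must be >= 1).
#' @param ref,alt character vectors of reference/alternate alleles.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character()) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n || length(alt) != n)
    stop("chrom, pos, ref and alt must have equal length")
  if (n > 0) {
    if (anyNA(pos) || any(pos < 1L))
      stop("pos must be a positive integer (1-based)")
    if (any(!nzchar(ref)) || any(ref == "."))
      stop("missing REF allele")
    if (any(!nzchar(alt)))
      stop("missing ALT allele")
  }
  tab <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  tab$key <- variant_key(tab)
  tab[!duplicated(tab$key), , drop = FALSE]
}

#' Encode variant keys
#'
#' @param tab a variant table.
#' @return Character vector of encoded (chrom, pos, ref, alt) keys.
#' @keywords internal
variant_key <- function(tab) {
  if (nrow(tab) == 0) return(character())
  paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = "\t")
}

#' Decode variant keys back into a variant table
#' @param keys character vector of encoded keys.
#' @keywords internal
keys_to_table <- function(keys) {
  if (length(keys) == 0) return(variant_table())
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             pos = as.integer(vapply(parts, `[[`, "", 2L)),
             ref = vapply(parts, `[[`, "", 3L),
             alt = vapply(parts, `[[`, "", 4L),
             key = keys,
             stringsAsFactors = FALSE)
}

# Deterministic sort: lexicographic chrom, then numeric pos, then ref, alt.
# The C collation keeps ordering locale-independent.
sort_variant_table <- function(tab) {
  if (nrow(tab) == 0) return(tab)
  o <- withr::with_collate("C", order(tab$chrom, tab$pos, tab$ref, tab$alt))
  tab[o, , drop = FALSE]
}

#' Create a call set
#'
#' A call set is a named, deduplicated collection of variant keys together
#' with the FILTER string of each variant, the unit of comparison throughout
#' the package. Filter strings are taken verbatim from the FILTER column
#' (`"PASS"`, `"q10"`, `"."`, ...); only `"PASS"` counts as passing.
#'
#' @param name source name, normally the file name.
#' @param variants a variant table (see [variant_table()]).
#' @param filter character vector of FILTER values, parallel to the rows of
#'   `variants`. Defaults to `"."` (non-PASS) for every variant.
#' @return An object of class `CallSet`.
#' @export
call_set <- function(name, variants = variant_table(), filter = NULL) {
  if (is.null(filter)) filter <- rep(".", nrow(variants))
  if (length(filter) != nrow(variants))
    stop("filter must have one value per variant")
  filter <- as.character(filter)
  filter[is.na(filter) | !nzchar(filter)] <- "."
  names(filter) <- variants$key
  structure(list(name = as.character(name), variants = variants,
                 filter = filter),
            class = "CallSet")
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("<CallSet> %s: %d unique variants (%d PASS)\n",
              x$name, nrow(x$variants), sum(x$filter == "PASS")))
  invisible(x)
}

#' Number of variants in a call set or golden set
#' @param x a `CallSet` or `GoldenSet`.
#' @return Integer count of unique variants.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Create a golden set
#'
#' The golden set is the trusted variant list used as ground truth when
#' benchmarking; it carries keys only (no filter status).
#'
#' @param variants a variant table.
#' @return An object of class `GoldenSet`.
#' @export
golden_set <- function(variants = variant_table()) {
  structure(list(variants = variants), class = "GoldenSet")
}

#' @export
print.GoldenSet <- function(x, ...) {
  cat(sprintf("<GoldenSet> %d unique variants\n", nrow(x$variants)))
  invisible(x)
}

#' Create a region set
#'
#' Sorted genomic intervals in BED convention: 0-based, half-open
#' `[start, end)`. Intervals are sorted by (chrom, start, end); overlapping
#' intervals are kept as given, not merged.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @return An object of class `RegionSet` (a sorted data.frame underneath).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer()) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(chrom) || length(end) != length(chrom))
    stop("chrom, start and end must have equal length")
  if (length(start) > 0) {
    if (anyNA(start) || anyNA(end))
      stop("region coordinates must be integers")
    if (any(start < 0L) || any(start >= end))
      stop("regions require 0 <= start < end")
  }
  tab <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  o <- withr::with_collate("C", order(tab$chrom, tab$start, tab$end))
  structure(list(intervals = tab[o, , drop = FALSE]), class = "RegionSet")
}

#' Number of intervals in a region set
#' @param rs a `RegionSet`.
#' @export
n_regions <- function(rs) nrow(rs$intervals)

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("<RegionSet> %d intervals on %d chromosome(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}
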