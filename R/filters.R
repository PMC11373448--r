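# Call-set filters: FILTER status, genomic regions, variant type, chromosome.
#
# Every filter returns a subset of its input call set and is idempotent.
# The pipeline applies them in the fixed order PASS -> regions -> chrom/type.

subset_callset <- function(cs, keep) {
  call_set(cs$name, cs$variants[keep, , drop = FALSE], cs$filter[keep])
}

#' Keep only PASS variants
#'
#' Retains exactly the variants whose FILTER column value is `"PASS"`;
#' `"."`, empty, and any caller-specific code count as non-PASS.
#'
#' @param cs a `CallSet`.
#' @return The filtered `CallSet`.
#' @export
filter_pass <- function(cs) {
  subset_callset(cs, unname(cs$filter) == "PASS")
}

# Membership rule shared by both region-filter implementations: a 1-based
# variant position p is inside a 0-based half-open interval [start, end) iff
# p - 1 is in [start, end), i.e. start < p <= end.  Only POS (the variant's
# anchor base) is tested, not the full REF span.

#' Filter a call set by genomic regions (naive algorithm)
#'
#' Reference implementation that checks every interval for every variant
#' (quadratic). [filter_regions_sorted()] is the production algorithm; this
#' one serves as its oracle and must give identical output on all inputs.
#'
#' @param cs a `CallSet`.
#' @param rs a `RegionSet`.
#' @param mode `"inside"` keeps variants falling within at least one interval;
#'   `"outside"` keeps the complement.
#' @return The filtered `CallSet`.
#' @export
filter_regions_naive <- function(cs, rs, mode = c("inside", "outside")) {
  mode <- match.arg(mode)
  iv <- rs$intervals
  tab <- cs$variants
  inside <- vapply(seq_len(nrow(tab)), function(i) {
    p0 <- tab$pos[i] - 1L
    any(iv$chrom == tab$chrom[i] & iv$start <= p0 & p0 < iv$end)
  }, logical(1))
  if (nrow(tab) == 0) inside <- logical(0)
  subset_callset(cs, if (mode == "inside") inside else !inside)
}

#' Filter a call set by genomic regions (single-pass sorted sweep)
#'
#' Sorts the variants, then walks the variant and interval streams of each
#' chromosome forward exactly once. A per-chromosome running maximum of the
#' interval ends handles overlapping and nested intervals without merging
#' them: once every interval starting at or before the variant's position has
#' been consumed, the variant is inside some interval iff that running
#' maximum end exceeds its 0-based position. Output is identical to
#' [filter_regions_naive()] on every input; complexity is linear in
#' variants + intervals per chromosome.
#'
#' @inheritParams filter_regions_naive
#' @return The filtered `CallSet`.
#' @export
filter_regions_sorted <- function(cs, rs, mode = c("inside", "outside")) {
  mode <- match.arg(mode)
  tab <- cs$variants
  iv <- rs$intervals
  inside <- logical(nrow(tab))
  o <- withr::with_collate("C", order(tab$chrom, tab$pos))
  for (chr in unique(tab$chrom[o])) {
    vi <- o[tab$chrom[o] == chr]           # variant rows, ascending pos
    ci <- which(iv$chrom == chr)           # intervals, ascending start
    starts <- iv$start[ci]; ends <- iv$end[ci]
    j <- 1L; max_end <- -1L
    for (i in vi) {
      p0 <- tab$pos[i] - 1L
      while (j <= length(ci) && starts[j] <= p0) {
        if (ends[j] > max_end) max_end <- ends[j]
        j <- j + 1L
      }
      inside[i] <- max_end > p0
    }
  }
  subset_callset(cs, if (mode == "inside") inside else !inside)
}

#' Filter a call set by variant type
#'
#' `"snp"` keeps single-base substitutions: one-character REF and ALT, both in
#' {A, C, G, T}. `"indel"` keeps length-changing variants: REF and ALT of
#' unequal length. Multi-base balanced substitutions (e.g. AT>GC) belong to
#' neither class.
#'
#' @param cs a `CallSet`.
#' @param vtype `"snp"` or `"indel"`.
#' @return The filtered `CallSet`.
#' @export
filter_variant_type <- function(cs, vtype = c("snp", "indel")) {
  vtype <- match.arg(vtype)
  tab <- cs$variants
  keep <- if (vtype == "snp") {
    nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
      tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T")
  } else {
    nchar(tab$ref) != nchar(tab$alt)
  }
  subset_callset(cs, keep)
}

#' Filter a call set by chromosome
#'
#' Keeps variants whose chromosome name is in `chroms` (exact string match;
#' `"chr1"` and `"1"` are distinct).
#'
#' @param cs a `CallSet`.
#' @param chroms character vector of chromosome names to keep.
#' @return The filtered `CallSet`.
#' @export
filter_chromosomes <- function(cs, chroms) {
  subset_callset(cs, cs$variants$chrom %in% chroms)
}
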