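# Synthetic inputs with controlled overlap structure.
#
# The generator emulates the structural side of a multi-caller comparison:
# which variants each file shares with which others, and what fraction pass
# the caller's filters.  Keys are sampled without replacement from
# (chrom in chr1..chr3, pos in 1..1e6, ref/alt in {A,C,G,T}, ref != alt) so
# all generated keys are distinct by construction, and every operation's
# expected result is computable in closed form from the returned manifest.

#' Design of a synthetic compare set
#'
#' @param set_names 2 to 6 file stems (files are written as `<name>.vcf`).
#' @param pattern_counts named integer vector: for each requested membership
#'   pattern, how many distinct variants realize it. Names are bitmask
#'   strings over `set_names` (`"110"` = shared by the first two sets only)
#'   or `" & "`-joined set names (`"A & B"`).
#' @param filter_mix fraction of non-PASS variants per file, recycled across
#'   files; the non-PASS count is `floor(n * filter_mix)`.
#' @param seed integer seed; the whole design is deterministic given it.
#' @return An `OverlapDesign` list.
#' @export
overlap_design <- function(set_names, pattern_counts, filter_mix = 0,
                           seed = 1L) {
  k <- length(set_names)
  if (k < 2 || k > 6) stop("set_names must name 2 to 6 sets")
  pats <- names(pattern_counts)
  if (is.null(pats)) stop("pattern_counts must be named")
  # accept "A & B" style names
  to_mask <- function(p) {
    if (grepl("^[01]+$", p) && nchar(p) == k) return(p)
    members <- trimws(strsplit(p, "&", fixed = TRUE)[[1]])
    bad <- setdiff(members, set_names)
    if (length(bad) > 0)
      stop(sprintf("unknown set name(s) in pattern '%s'", p))
    paste(as.integer(set_names %in% members), collapse = "")
  }
  names(pattern_counts) <- vapply(pats, to_mask, "")
  if (any(pattern_counts < 0)) stop("pattern_counts must be non-negative")
  if (any(names(pattern_counts) == paste(rep("0", k), collapse = "")))
    stop("the empty membership pattern cannot be requested")
  filter_mix <- rep_len(filter_mix, k)
  if (any(filter_mix < 0 | filter_mix > 1))
    stop("filter_mix fractions must be in [0, 1]")
  structure(list(set_names = set_names,
                 pattern_counts = pattern_counts,
                 filter_mix = filter_mix,
                 seed = as.integer(seed)),
            class = "OverlapDesign")
}

# n distinct variant keys, deterministic under the active RNG state
sample_variant_keys <- function(n) {
  if (n == 0) return(variant_table())
  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); seen <- character(0)
  bases <- c("A", "C", "G", "T")
  while (length(seen) < n) {
    m <- n - length(seen)
    ch <- sample(paste0("chr", 1:3), m, replace = TRUE)
    po <- sample.int(1000000L, m, replace = TRUE)
    rf <- sample(bases, m, replace = TRUE)
    al <- vapply(rf, function(r) sample(setdiff(bases, r), 1), "")
    key <- paste(ch, po, rf, al, sep = "\t")
    new <- !duplicated(key) & !(key %in% seen)
    chrom <- c(chrom, ch[new]); pos <- c(pos, po[new])
    ref <- c(ref, rf[new]); alt <- c(alt, unname(al[new]))
    seen <- c(seen, key[new])
  }
  variant_table(chrom, pos, ref, alt)
}

#' Generate synthetic VCF files realizing a designed overlap structure
#'
#' Writes one plain-text VCF per set name; the files' Venn tally equals the
#' design's pattern counts exactly. Per file, the `floor(n * filter_mix)`
#' variants marked non-PASS (FILTER `"q10"`) are chosen deterministically
#' under the design seed. The returned manifest records every file's exact
#' key set and filter assignment, so expected values of any downstream
#' analysis can be derived from it independently of the readers.
#'
#' @param design an [overlap_design()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a manifest: list with `files` (named paths), `keys`
#'   (named list of per-file variant tables), `filters` (named list of
#'   per-file FILTER vectors) and `patterns` (keys per membership pattern).
#' @export
synth_vcfs <- function(design, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- length(design$set_names)
  withr::with_seed(design$seed, {
    total <- sum(design$pattern_counts)
    pool <- sample_variant_keys(total)
    idx <- 0L
    pattern_keys <- list()
    for (p in names(design$pattern_counts)) {
      n <- design$pattern_counts[[p]]
      pattern_keys[[p]] <- pool[seq_len(n) + idx, , drop = FALSE]
      idx <- idx + n
    }
    files <- character(0); keys <- list(); filters <- list()
    for (i in seq_len(k)) {
      nm <- design$set_names[i]
      in_pat <- vapply(names(pattern_keys),
                       function(p) substr(p, i, i) == "1", TRUE)
      tab <- do.call(rbind, c(pattern_keys[in_pat], list(variant_table())))
      tab <- sort_variant_table(tab)
      filt <- rep("PASS", nrow(tab))
      n_fail <- floor(nrow(tab) * design$filter_mix[i])
      if (n_fail > 0)
        filt[sample.int(nrow(tab), n_fail)] <- "q10"
      fname <- paste0(nm, ".vcf")
      path <- file.path(out_dir, fname)
      writeLines(c("##fileformat=VCFv4.2",
                   paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", sep = "\t"),
                   if (nrow(tab) > 0)
                     paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".",
                           filt, ".", sep = "\t")),
                 path)
      files[fname] <- path
      keys[[fname]] <- tab
      filters[[fname]] <- stats::setNames(filt, tab$key)
    }
    invisible(list(files = files, keys = keys, filters = filters,
                   patterns = pattern_keys))
  })
}

#' Generate a synthetic BED file with known coverage
#'
#' Draws `n_intervals` non-degenerate intervals uniformly within the given
#' chromosome sizes, writes them sorted, and returns the exact set of covered
#' 1-based positions per chromosome for oracle tests.
#'
#' @param n_intervals number of intervals.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param path output BED path.
#' @param seed integer seed.
#' @param max_len maximum interval length.
#' @return Invisibly, a manifest: list with `path`, `regions` (the
#'   `RegionSet`) and `covered` (named list of covered 1-based positions).
#' @export
synth_bed <- function(n_intervals, chrom_sizes, path, seed = 1L,
                      max_len = 50L) {
  withr::with_seed(seed, {
    if (n_intervals > 0) {
      chrom <- sample(names(chrom_sizes), n_intervals, replace = TRUE)
      start <- vapply(chrom, function(ch)
        sample.int(chrom_sizes[[ch]], 1) - 1L, 0L)
      len <- sample.int(max_len, n_intervals, replace = TRUE)
      end <- pmin(start + len, vapply(chrom, function(ch)
        as.integer(chrom_sizes[[ch]]), 0L))
      end <- pmax(end, start + 1L)
      rs <- region_set(chrom, start, end)
    } else {
      rs <- region_set()
    }
    iv <- rs$intervals
    writeLines(if (nrow(iv) > 0)
                 paste(iv$chrom, iv$start, iv$end, sep = "\t")
               else character(), path)
    covered <- lapply(split(iv, iv$chrom), function(d)
      sort(unique(unlist(Map(function(s, e) seq.int(s + 1L, e), d$start,
                             d$end)))))
    invisible(list(path = path, regions = rs, covered = covered))
  })
}

#' Generate a synthetic metadata CSV
#'
#' Assigns each file a value from every column's value cycle, recycling
#' values in order (file i gets `values[((i - 1) %% length) + 1]`), and
#' writes an RFC-4180 CSV with the mandatory `FILENAME` column.
#'
#' @param filenames character vector of compare-set file names.
#' @param columns named list: column name -> character vector of values to
#'   cycle over the files.
#' @param path output CSV path.
#' @return Invisibly, the metadata as a `MetadataTable`.
#' @export
synth_metadata <- function(filenames, columns, path) {
  if (length(filenames) == 0) stop("filenames must be non-empty")
  if (is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("columns must be a named list")
  tab <- data.frame(FILENAME = filenames, stringsAsFactors = FALSE)
  for (col in names(columns))
    tab[[col]] <- rep_len(columns[[col]], length(filenames))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  class(tab) <- c("MetadataTable", "data.frame")
  invisible(tab)
}
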