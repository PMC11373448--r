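# Input/output: VCF (plain, gzip, zip), BED, CSV.

# Typed conditions so the pipeline can collect and classify input problems.
io_error <- function(class, msg, file = NULL, call. = FALSE) {
  stop(errorCondition(msg, file = file,
                      class = c(class, "vcfcompare_error", "error")))
}

#' @keywords internal
format_error <- function(msg, file = NULL)
  io_error("vcfcompare_format_error", msg, file)
size_error <- function(msg, file = NULL)
  io_error("vcfcompare_size_error", msg, file)
schema_error <- function(msg, file = NULL)
  io_error("vcfcompare_schema_error", msg, file)
coverage_error <- function(msg, file = NULL)
  io_error("vcfcompare_coverage_error", msg, file)

# Sniff compression from magic bytes, not the file extension.
sniff_compression <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    return("gzip")
  if (length(magic) >= 4 && rawToChar(magic[1:2]) == "PK")
    return("zip")
  "plain"
}

# Return a path to plain or gzip VCF text, extracting zip archives (which must
# contain exactly one member) to a temporary file.
resolve_vcf_path <- function(path) {
  comp <- sniff_compression(path)
  if (comp != "zip") return(path)
  members <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e)
                        io_error("vcfcompare_decompression_error",
                                 sprintf("cannot read zip archive '%s': %s",
                                         basename(path), conditionMessage(e)),
                                 basename(path)))
  if (nrow(members) != 1)
    io_error("vcfcompare_decompression_error",
             sprintf("zip archive '%s' must contain exactly one file, found %d",
                     basename(path), nrow(members)), basename(path))
  exdir <- tempfile("vcfzip")
  dir.create(exdir)
  utils::unzip(path, exdir = exdir)
  file.path(exdir, members$Name[1])
}

# A VCF must carry a #CHROM header line before any data line.
validate_vcf_header <- function(path, file_label) {
  con <- if (sniff_compression(path) == "gzip") gzfile(path, "rt")
         else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                     error = function(e)
                       io_error("vcfcompare_decompression_error",
                                sprintf("cannot decompress '%s': %s",
                                        file_label, conditionMessage(e)),
                                file_label))
    if (length(line) == 0)
      format_error(sprintf("'%s' has no #CHROM header line", file_label),
                   file_label)
    if (startsWith(line, "#CHROM")) return(invisible(TRUE))
    if (!startsWith(line, "#"))
      format_error(sprintf("'%s' has a data line before the #CHROM header",
                           file_label), file_label)
  }
}

#' Read a VCF file into a call set
#'
#' Accepts plain, GZip- or Zip-compressed VCF text (compression detected from
#' magic bytes, not the extension; a Zip archive must contain exactly one
#' member). Only CHROM/POS/REF/ALT/FILTER are retained. Multi-allelic records
#' (comma-separated ALT) are split into one variant per alternate allele, each
#' carrying the record's FILTER value. Duplicate (chrom, pos, ref, alt)
#' records are silently collapsed, keeping the first record's FILTER.
#' Symbolic ALT alleles (`<DEL>` and the like) are kept verbatim.
#'
#' @param path path to the VCF file.
#' @param max_size maximum accepted file size in bytes (default 200 MB).
#' @param name name to give the call set; defaults to the file's basename.
#' @return A [call_set()].
#' @export
read_vcf <- function(path, max_size = 200 * 1024^2, name = basename(path)) {
  if (!file.exists(path))
    format_error(sprintf("file '%s' does not exist", name), name)
  if (file.size(path) > max_size)
    size_error(sprintf("'%s' exceeds the size limit of %s bytes (%s bytes)",
                       name, format(max_size, scientific = FALSE),
                       format(file.size(path), scientific = FALSE)), name)
  real <- resolve_vcf_path(path)
  validate_vcf_header(real, name)
  v <- tryCatch(
    vcfR::read.vcfR(real, verbose = FALSE, checkFile = FALSE,
                    convertNA = FALSE, check_keys = FALSE),
    error = function(e)
      format_error(sprintf("cannot parse VCF '%s': %s", name,
                           conditionMessage(e)), name))
  fix <- v@fix
  if (nrow(fix) == 0)
    return(call_set(name, variant_table()))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos) || any(pos < 1L))
    format_error(sprintf("'%s' contains a non-positive or non-integer POS",
                         name), name)
  ref <- fix[, "REF"]
  if (any(is.na(ref)) || any(ref == ".") || any(!nzchar(ref)))
    format_error(sprintf("'%s' contains a missing REF allele", name), name)
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | !nzchar(filt)] <- "."
  # split multi-allelic ALT into one key per alternate allele
  alts <- strsplit(alt, ",", fixed = TRUE)
  reps <- lengths(alts)
  tab <- data.frame(chrom = rep(fix[, "CHROM"], reps),
                    pos = rep(pos, reps),
                    ref = toupper(rep(ref, reps)),
                    alt = toupper(unlist(alts, use.names = FALSE)),
                    stringsAsFactors = FALSE)
  filt <- rep(filt, reps)
  tab$key <- variant_key(tab)
  keep <- !duplicated(tab$key)
  call_set(name, tab[keep, , drop = FALSE], filt[keep])
}

#' Read one or more VCF files into a golden set
#'
#' Pools the deduplicated variant keys of all files by union. An empty path
#' list yields an empty golden set (benchmarking then refuses to run).
#'
#' @inheritParams read_vcf
#' @param paths character vector of VCF paths.
#' @return A [golden_set()].
#' @export
read_golden <- function(paths, max_size = 200 * 1024^2) {
  tabs <- lapply(paths, function(p) read_vcf(p, max_size)$variants)
  if (length(tabs) == 0) return(golden_set())
  pooled <- do.call(rbind, tabs)
  golden_set(pooled[!duplicated(pooled$key), , drop = FALSE])
}

#' Read BED files into a region set
#'
#' Reads whitespace-delimited BED (>= 3 columns, 0-based half-open
#' coordinates), pools the intervals of all files and sorts them. Track/header
#' lines (`track`, `browser`, `#`) and blank lines are skipped.
#'
#' @param paths character vector of BED paths.
#' @return A [region_set()].
#' @export
read_bed <- function(paths) {
  chrom <- character(); start <- integer(); end <- integer()
  for (p in paths) {
    if (!file.exists(p))
      format_error(sprintf("file '%s' does not exist", basename(p)),
                   basename(p))
    lines <- readLines(p, warn = FALSE)
    for (i in seq_along(lines)) {
      line <- lines[i]
      if (!nzchar(trimws(line)) || startsWith(line, "#") ||
          startsWith(line, "track") || startsWith(line, "browser")) next
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) < 3)
        format_error(sprintf("'%s' line %d: expected >= 3 BED columns",
                             basename(p), i), basename(p))
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e))
        format_error(sprintf("'%s' line %d: non-integer coordinates",
                             basename(p), i), basename(p))
      if (s < 0 || s >= e)
        format_error(sprintf("'%s' line %d: requires 0 <= start < end",
                             basename(p), i), basename(p))
      chrom <- c(chrom, f[1]); start <- c(start, s); end <- c(end, e)
    }
  }
  region_set(chrom, start, end)
}

#' Read a metadata table describing the compare set
#'
#' The CSV must contain a column named exactly `FILENAME` with unique values,
#' and every compare-set file name must appear under it. All other columns are
#' free-form file properties usable for grouping, labeling and plot styling.
#'
#' @param path path to the CSV file.
#' @param compare_names character vector of compare-set file names that must
#'   be covered; pass `character()` to skip the coverage check.
#' @return A data.frame of class `MetadataTable`.
#' @export
read_metadata <- function(path, compare_names = character()) {
  if (!file.exists(path))
    format_error(sprintf("file '%s' does not exist", basename(path)),
                 basename(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!"FILENAME" %in% names(tab))
    schema_error(sprintf("metadata '%s' has no FILENAME column",
                         basename(path)), basename(path))
  dup <- tab$FILENAME[duplicated(tab$FILENAME)]
  if (length(dup) > 0)
    schema_error(sprintf("metadata '%s' lists duplicate FILENAME value(s): %s",
                         basename(path), paste(unique(dup), collapse = ", ")),
                 basename(path))
  missing <- setdiff(compare_names, tab$FILENAME)
  if (length(missing) > 0)
    coverage_error(sprintf(
      "metadata '%s' does not cover compare-set file(s): %s",
      basename(path), paste(missing, collapse = ", ")), basename(path))
  class(tab) <- c("MetadataTable", "data.frame")
  tab
}

#' Property columns of a metadata table
#' @param meta a `MetadataTable`.
#' @return Character vector of column names other than `FILENAME`.
#' @export
metadata_columns <- function(meta) setdiff(names(meta), "FILENAME")

#' Write variant keys as a compressed VCF file
#'
#' Writes a minimal, GZip-compressed, header-valid VCF sorted by
#' (chrom, pos, ref, alt). Reading the output with [read_vcf()] recovers
#' exactly the input key set (round-trip).
#'
#' @param variants a variant table, or an object with a `$variants` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  if (is.list(variants) && !is.data.frame(variants) &&
      !is.null(variants$variants))
    variants <- variants$variants
  tab <- sort_variant_table(variants)
  con <- tryCatch(gzfile(path, "wb"),
                  error = function(e)
                    io_error("vcfcompare_io_error",
                             sprintf("cannot write '%s'", path), path))
  on.exit(close(con))
  header <- c("##fileformat=VCFv4.2",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- if (nrow(tab) == 0) character() else
    paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".", ".", ".",
          sep = "\t")
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a labeled table as CSV
#'
#' RFC-4180 CSV with a header row; labels and cell values round-trip
#' losslessly (fields containing commas or quotes are quoted).
#'
#' @param table a data.frame or matrix. Matrix row names become a leading
#'   column named after `row_label`.
#' @param path output path.
#' @param row_label column name used for matrix row names.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, row_label = "name") {
  if (is.matrix(table)) {
    df <- as.data.frame(table, stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(rownames(table))) {
      df <- cbind(stats::setNames(data.frame(rownames(table),
                                             stringsAsFactors = FALSE),
                                  row_label),
                  df)
    }
    table <- df
  }
  tryCatch(utils::write.csv(table, path, row.names = FALSE, quote = TRUE),
           error = function(e)
             io_error("vcfcompare_io_error",
                      sprintf("cannot write '%s': %s", path,
                              conditionMessage(e)), path))
  invisible(path)
}
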