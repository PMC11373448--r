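# Shared test helpers: tiny call sets, on-disk VCF/BED writers, random
# instances for the property tests, and an independent region-membership
# oracle used to cross-check both filter implementations.

tab_of <- function(chrom, pos, ref = "A", alt = "G") {
  n <- length(pos)
  variant_table(rep_len(chrom, n), pos, rep_len(ref, n), rep_len(alt, n))
}

cs_of <- function(name, chrom, pos, ref = "A", alt = "G", filter = "PASS") {
  tab <- tab_of(chrom, pos, ref, alt)
  call_set(name, tab, rep_len(filter, nrow(tab)))
}

# a call set from integer "variant ids" (chr1, pos = id); handy for set logic
cs_ids <- function(name, ids, filter = "PASS") {
  cs_of(name, "chr1", as.integer(ids), filter = filter)
}

write_vcf_text <- function(path, records,
                           header = c("##fileformat=VCFv4.2",
                                      paste("#CHROM", "POS", "ID", "REF",
                                            "ALT", "QUAL", "FILTER", "INFO",
                                            sep = "\t"))) {
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, filter = "PASS") {
  paste(chrom, pos, ".", ref, alt, ".", filter, ".", sep = "\t")
}

gzip_file <- function(src, dst) {
  con <- gzfile(dst, "wb")
  writeLines(readLines(src), con)
  close(con)
  dst
}

zip_file <- function(src, dst) {
  code <- sprintf(
    "import zipfile,sys; zipfile.ZipFile('%s','w').write('%s','%s')",
    dst, src, basename(src))
  status <- system2("python", c("-c", shQuote(code)))
  stopifnot(status == 0)
  dst
}

# independent membership oracle: 1-based position p is covered iff some
# interval on the same chromosome has start < p <= end
oracle_inside <- function(cs, rs) {
  tab <- cs$variants
  iv <- rs$intervals
  vapply(seq_len(nrow(tab)), function(i)
    any(iv$chrom == tab$chrom[i] &
          iv$start < tab$pos[i] & tab$pos[i] <= iv$end),
    logical(1))
}

random_region_instance <- function(n_var, n_int, max_pos = 120L) {
  cs <- cs_of("rand", sample(c("chr1", "chr2"), n_var, replace = TRUE),
              sample.int(max_pos, n_var, replace = TRUE))
  if (n_int > 0) {
    start <- sample.int(max_pos, n_int, replace = TRUE) - 1L
    len <- sample.int(15L, n_int, replace = TRUE)
    rs <- region_set(sample(c("chr1", "chr2"), n_int, replace = TRUE),
                     start, start + len)
  } else {
    rs <- region_set()
  }
  list(cs = cs, rs = rs)
}

expect_same_keys <- function(a, b) {
  expect_setequal(as_key_vec(a), as_key_vec(b))
}

as_key_vec <- function(x) {
  if (inherits(x, c("CallSet", "GoldenSet"))) x$variants$key
  else if (is.data.frame(x)) x$key
  else as.character(x)
}
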