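# Reading and writing VCF/BED/CSV inputs and the variant identity they carry.

test_that("a VCF parses into deduplicated exact-match keys with filter status", {
  f <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      c(vcf_record("chr1", 100, "A", "G", "PASS"),
                        vcf_record("chr1", 200, "C", "T", "q10")))
  cs <- read_vcf(f)
  expect_s3_class(cs, "CallSet")
  expect_equal(n_variants(cs), 2L)
  expect_equal(unname(cs$filter[cs$variants$pos == 100]), "PASS")
  expect_equal(unname(cs$filter[cs$variants$pos == 200]), "q10")

  # duplicates collapse to one key; the first record's FILTER wins
  f2 <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                       c(vcf_record("chr1", 100, "A", "G", "PASS"),
                         vcf_record("chr1", 100, "a", "g", "q10"),
                         vcf_record("chr1", 100, "A", "G", ".")))
  cs2 <- read_vcf(f2)
  expect_equal(n_variants(cs2), 1L)
  expect_equal(unname(cs2$filter), "PASS")
})

test_that("multi-allelic ALT splits into one key per alternate allele", {
  f <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      vcf_record("chr2", 50, "A", "G,T", "PASS"))
  cs <- read_vcf(f)
  expect_equal(n_variants(cs), 2L)
  expect_setequal(cs$variants$alt, c("G", "T"))
  expect_equal(unname(cs$filter), c("PASS", "PASS"))
})

test_that("gzip and zip encodings of the same text yield identical call sets", {
  plain <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                          c(vcf_record("chr1", 100, "A", "G"),
                            vcf_record("chr2", 7, "AT", "A", "q10")))
  gz <- gzip_file(plain, withr::local_tempfile(fileext = ".vcf.gz"))
  zp <- zip_file(plain, withr::local_tempfile(fileext = ".vcf.zip"))
  cs_plain <- read_vcf(plain, name = "x")
  cs_gz <- read_vcf(gz, name = "x")
  cs_zip <- read_vcf(zp, name = "x")
  expect_identical(cs_plain$variants, cs_gz$variants)
  expect_identical(cs_plain$variants, cs_zip$variants)
  expect_identical(unname(cs_plain$filter), unname(cs_zip$filter))
})

test_that("REF/ALT are uppercased but chromosome names stay verbatim", {
  f <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      c(vcf_record("1", 10, "a", "t"),
                        vcf_record("chr1", 10, "A", "T")))
  cs <- read_vcf(f)
  expect_equal(n_variants(cs), 2L)  # "1" != "chr1"
  expect_true(all(cs$variants$ref == "A"))
  expect_true(all(cs$variants$alt == "T"))
})

test_that("symbolic ALT alleles pass through verbatim", {
  f <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      vcf_record("chr1", 500, "A", "<DEL>", "PASS"))
  cs <- read_vcf(f)
  expect_equal(cs$variants$alt, "<DEL>")
})

test_that("malformed or oversized inputs raise typed errors naming the file", {
  no_header <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_record("chr1", 1, "A", "G"), no_header)
  expect_error(read_vcf(no_header, name = "bad.vcf"),
               class = "vcfcompare_format_error")
  expect_error(read_vcf(no_header, name = "bad.vcf"), "bad.vcf")

  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines("##fileformat=VCFv4.2", empty)
  expect_error(read_vcf(empty), class = "vcfcompare_format_error")

  big <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                        vcf_record("chr1", 1, "A", "G"))
  expect_error(read_vcf(big, max_size = 10), class = "vcfcompare_size_error")

  expect_error(read_vcf(withr::local_tempfile(fileext = ".vcf")),
               class = "vcfcompare_format_error")  # nonexistent file
})

test_that("zip archives must contain exactly one member", {
  a <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      vcf_record("chr1", 1, "A", "G"))
  b <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                      vcf_record("chr1", 2, "A", "G"))
  two <- withr::local_tempfile(fileext = ".zip")
  code <- sprintf(paste0("import zipfile\nz=zipfile.ZipFile('%s','w')\n",
                         "z.write('%s','a.vcf')\nz.write('%s','b.vcf')\n",
                         "z.close()"), two, a, b)
  stopifnot(system2("python", c("-c", shQuote(code))) == 0)
  expect_error(read_vcf(two), class = "vcfcompare_decompression_error")
})

test_that("golden sets pool files by union and tolerate an empty path list", {
  f1 <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                       c(vcf_record("chr1", 1, "A", "G"),
                         vcf_record("chr1", 2, "A", "G")))
  f2 <- write_vcf_text(withr::local_tempfile(fileext = ".vcf"),
                       c(vcf_record("chr1", 2, "A", "G"),
                         vcf_record("chr1", 3, "A", "G")))
  g <- read_golden(c(f1, f2))
  expect_equal(sort(g$variants$pos), c(1L, 2L, 3L))
  expect_equal(n_variants(read_golden(character())), 0L)
})

test_that("BED files pool, sort and validate with line numbers", {
  b1 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2 5 10", "chr1 99 200"), b1)
  b2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr3\t1\t2", "chr1\t50\t60"), b2)
  rs <- read_bed(c(b1, b2))
  expect_equal(n_regions(rs), 5L)
  iv <- rs$intervals
  expect_true(!is.unsorted(order(iv$chrom, iv$start, iv$end)))
  expect_equal(iv$start[iv$chrom == "chr1"], c(0L, 50L, 99L))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1 0 10", "chr1 x 20"), bad)
  expect_error(read_bed(bad), "line 2")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1 10 10", bad2)
  expect_error(read_bed(bad2), class = "vcfcompare_format_error")
  bad3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1 10", bad3)
  expect_error(read_bed(bad3), "3 BED columns")
})

test_that("metadata requires a unique FILENAME column covering the compare set", {
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FILENAME,aligner,caller",
               "a.vcf,BWA,HC", "b.vcf,BWA,VS",
               "c.vcf,Bowtie2,HC", "d.vcf,Bowtie2,VS"), ok)
  meta <- read_metadata(ok, c("a.vcf", "b.vcf", "c.vcf", "d.vcf"))
  expect_setequal(metadata_columns(meta), c("aligner", "caller"))

  no_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("file,aligner", "a.vcf,BWA"), no_col)
  expect_error(read_metadata(no_col), class = "vcfcompare_schema_error")

  expect_error(read_metadata(ok, c("a.vcf", "e.vcf")),
               class = "vcfcompare_coverage_error")
  expect_error(read_metadata(ok, c("a.vcf", "e.vcf")), "e.vcf")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FILENAME,x", "a.vcf,1", "a.vcf,2"), dup)
  expect_error(read_metadata(dup), class = "vcfcompare_schema_error")
})

test_that("variant VCF output is sorted, compressed and round-trips", {
  tab <- variant_table(c("chr2", "chr1", "chr1"), c(5L, 300L, 4L),
                       c("A", "C", "AT"), c("G", "T", "A"))
  out <- withr::local_tempfile(fileext = ".vcf.gz")
  write_variants_vcf(tab, out)
  expect_equal(sniff_compression <- readBin(out, "raw", 2),
               as.raw(c(0x1f, 0x8b)))
  back <- read_vcf(out)
  expect_setequal(back$variants$key, tab$key)
  lines <- readLines(gzfile(out))
  body <- lines[!startsWith(lines, "#")]
  # records sorted by (chrom, pos, ref, alt): chr1:4, chr1:300, chr2:5
  expect_equal(vapply(strsplit(body, "\t"), `[[`, "", 1),
               c("chr1", "chr1", "chr2"))
  expect_equal(as.integer(vapply(strsplit(body, "\t"), `[[`, "", 2)),
               c(4L, 300L, 5L))

  empty_out <- withr::local_tempfile(fileext = ".vcf.gz")
  write_variants_vcf(variant_table(), empty_out)
  expect_equal(n_variants(read_vcf(empty_out)), 0L)
})

test_that("CSV tables round-trip labels and values, quoting where needed", {
  df <- data.frame(name = c("a, with comma", "b"), count = c(2L, 1L),
                   stringsAsFactors = FALSE)
  out <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(df, out)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(back$name, df$name)
  expect_equal(back$count, df$count)

  empty <- data.frame(name = character(), count = integer())
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(empty, out2)
  expect_equal(nrow(utils::read.csv(out2)), 0L)

  m <- matrix(1:4, 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  out3 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(m, out3)
  back3 <- utils::read.csv(out3)
  expect_equal(back3$c1, c(1L, 2L))
  expect_equal(back3$name, c("r1", "r2"))
})
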