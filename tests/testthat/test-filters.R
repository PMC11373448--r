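# Filters: PASS status, region membership (both algorithms), type, chromosome.

test_that("PASS filtering keeps exactly FILTER == PASS and is idempotent", {
  cs <- call_set("x", tab_of("chr1", 1:3), c("PASS", "q10", "."))
  kept <- filter_pass(cs)
  expect_equal(kept$variants$pos, 1L)
  expect_identical(filter_pass(kept)$variants, kept$variants)

  all_pass <- cs_ids("y", 1:5)
  expect_identical(filter_pass(all_pass)$variants, all_pass$variants)
})

test_that("region membership anchors POS with start < pos <= end", {
  rs <- region_set("chr1", 99L, 200L)
  for (fn in list(filter_regions_naive, filter_regions_sorted)) {
    expect_equal(fn(cs_of("v", "chr1", 150L), rs, "inside")$variants$pos,
                 150L)
    expect_equal(n_variants(fn(cs_of("v", "chr1", 99L), rs, "inside")), 0L)
    expect_equal(fn(cs_of("v", "chr1", 100L), rs, "inside")$variants$pos,
                 100L)
    expect_equal(fn(cs_of("v", "chr1", 200L), rs, "inside")$variants$pos,
                 200L)
    expect_equal(n_variants(fn(cs_of("v", "chr1", 201L), rs, "inside")), 0L)
    expect_equal(n_variants(fn(cs_of("v", "chr2", 150L), rs, "inside")), 0L)
  }
})

test_that("inside and outside partition the call set exactly", {
  withr::local_seed(11)
  inst <- random_region_instance(50, 10)
  for (fn in list(filter_regions_naive, filter_regions_sorted)) {
    ins <- fn(inst$cs, inst$rs, "inside")
    outs <- fn(inst$cs, inst$rs, "outside")
    expect_setequal(c(ins$variants$key, outs$variants$key),
                    inst$cs$variants$key)
    expect_length(intersect(ins$variants$key, outs$variants$key), 0)
    # brute-force check against the independent oracle
    expect_setequal(ins$variants$key,
                    inst$cs$variants$key[oracle_inside(inst$cs, inst$rs)])
  }
})

test_that("the sorted sweep equals the naive algorithm on tricky layouts", {
  # nested and adjacent intervals, variant kept once despite double cover
  rs <- region_set(c("chr1", "chr1", "chr1"), c(0L, 50L, 60L),
                   c(100L, 60L, 70L))
  cs <- cs_of("v", "chr1", c(55L, 60L, 61L, 100L, 101L))
  expect_identical(filter_regions_sorted(cs, rs, "inside")$variants,
                   filter_regions_naive(cs, rs, "inside")$variants)
  expect_equal(filter_regions_sorted(cs, rs, "inside")$variants$pos,
               c(55L, 60L, 61L, 100L))

  # empty region set: inside keeps nothing, outside keeps all
  expect_equal(n_variants(filter_regions_sorted(cs, region_set(),
                                                "inside")), 0L)
  expect_identical(filter_regions_sorted(cs, region_set(),
                                         "outside")$variants, cs$variants)
})

test_that("the sorted sweep matches the naive oracle on random instances", {
  withr::local_seed(42)
  for (rep in 1:50) {
    inst <- random_region_instance(sample.int(60, 1), sample.int(12, 1) - 1L)
    for (mode in c("inside", "outside")) {
      expect_identical(
        filter_regions_sorted(inst$cs, inst$rs, mode)$variants$key,
        filter_regions_naive(inst$cs, inst$rs, mode)$variants$key)
    }
  }
})

test_that("variant-type filtering splits SNPs from indels", {
  tab <- variant_table(rep("chr1", 5), 1:5,
                       c("A", "C", "AT", "G", "AT"),
                       c("G", "T", "A", "GTT", "GC"))
  cs <- call_set("x", tab)
  snp <- filter_variant_type(cs, "snp")
  ind <- filter_variant_type(cs, "indel")
  expect_equal(snp$variants$pos, c(1L, 2L))
  expect_equal(ind$variants$pos, c(3L, 4L))  # AT>GC is neither class
  expect_equal(n_variants(filter_variant_type(snp, "indel")), 0L)
  # symbolic ALT counts as length-changing
  sym <- call_set("s", variant_table("chr1", 9L, "A", "<DEL>"))
  expect_equal(n_variants(filter_variant_type(sym, "indel")), 1L)
})

test_that("chromosome filtering is exact-match and handles degenerate lists", {
  cs <- cs_of("x", c("chr1", "chr1", "chr2"), c(1L, 2L, 3L))
  expect_equal(n_variants(filter_chromosomes(cs, "chr1")), 2L)
  expect_equal(n_variants(filter_chromosomes(cs, "1")), 0L)
  expect_equal(n_variants(filter_chromosomes(cs, character())), 0L)
  expect_identical(filter_chromosomes(cs, c("chr1", "chr2"))$variants,
                   cs$variants)
})

test_that("every filter is a subset operation and idempotent", {
  withr::local_seed(5)
  inst <- random_region_instance(40, 6)
  cs <- call_set(inst$cs$name, inst$cs$variants,
                 sample(c("PASS", "q10", "."), n_variants(inst$cs),
                        replace = TRUE))
  filters <- list(
    function(x) filter_pass(x),
    function(x) filter_regions_sorted(x, inst$rs, "inside"),
    function(x) filter_regions_sorted(x, inst$rs, "outside"),
    function(x) filter_variant_type(x, "snp"),
    function(x) filter_chromosomes(x, "chr1"))
  for (f in filters) {
    once <- f(cs)
    expect_true(all(once$variants$key %in% cs$variants$key))
    expect_identical(f(once)$variants, once$variants)
  }
})
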