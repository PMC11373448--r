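# vcfcompare

Set-wise comparison, filtering, grouping and benchmarking of VCF variant
call sets, for R.

When the same sequencing reads are pushed through different
aligner/caller pipelines, the resulting VCF files agree on most variants
and disagree on the rest — and deciding which pipeline (or combination)
to trust requires comparing the files as *sets*. `vcfcompare` is built
for that job: it treats every variant as an exact-match identity key

```
(CHROM, POS, REF, ALT)
```

(REF/ALT uppercased, chromosome names verbatim, multi-allelic records
split into one key per alternate allele, duplicates collapsed) and then
offers the standard comparisons on those key sets:

- **Filtering** — keep only `FILTER == PASS` variants; keep variants
  inside or outside BED regions (1-based position *p* is inside a
  0-based half-open interval `[start, end)` iff `start < p <= end`),
  using a single-pass sorted sweep that is linear in variants +
  intervals, with a naive quadratic implementation kept as its oracle;
  keep only SNPs or indels; keep chosen chromosomes.
- **Grouping** — partition files by the value tuples of metadata columns
  (a CSV with a `FILENAME` column) and pool each group by *union*
  (variant in any member), *intersection* (in all members) or *majority*
  (in strictly more than 50% of members).
- **Comparison** — Venn tallies of 2–6 sets (every variant of the union
  assigned to exactly one membership pattern), the intersection of all
  sets exported as a compressed VCF, and pairwise Jaccard similarity
  `J(A, B) = |A ∩ B| / |A ∪ B|` with average-linkage hierarchical
  clustering on `1 − J` for clustergram ordering.
- **Benchmarking** — against a pooled golden set *G*, each compare set
  *C* gets

  ```
  precision = |C ∩ G| / |C|        recall = |C ∩ G| / |G|
  ```

  with the raw counts carried alongside the ratios.
- **Reporting** — count tables and pivots, histogram, Venn/pseudo-Venn,
  clustergram and precision–recall figures as PNG, each with a CSV
  sibling of its underlying numbers; figures are never the only record.

A pipeline orchestrator (`run_analysis()`) runs one request in a fixed
stage order — validate → load → PASS filter → region filter →
chromosome/type filter → group → analyze → export — and refuses to
analyze anything if any input failed to load. A synthetic-data generator
(`overlap_design()`, `synth_vcfs()`, `synth_bed()`, `synth_metadata()`)
produces small VCF/BED/CSV inputs whose overlap structure is known
exactly, so every operation can be verified against a manifest.

## Worked example

Generate four synthetic call sets that share a 40-variant core (think
two aligners × two callers), then compare and benchmark them:

```r
library(vcfcompare)

design <- overlap_design(
  set_names = c("bwa_hc", "bwa_vs", "bt2_hc", "bt2_vs"),
  pattern_counts = c("1111" = 40, "1100" = 6, "0011" = 2, "1010" = 4,
                     "0101" = 3, "1000" = 5, "0100" = 4, "0010" = 3,
                     "0001" = 2),
  filter_mix = 0.2, seed = 42)
manifest <- synth_vcfs(design, "demo")
callsets <- lapply(manifest$files, read_vcf)
count_table(callsets)
#>                  name n_variants
#> bwa_hc.vcf bwa_hc.vcf         55
#> bwa_vs.vcf bwa_vs.vcf         53
#> bt2_hc.vcf bt2_hc.vcf         49
#> bt2_vs.vcf bt2_vs.vcf         47

callsets <- lapply(callsets, filter_pass)   # 20% were marked non-PASS
round(unclass(jaccard_matrix(callsets)), 2)
#>            bwa_hc.vcf bwa_vs.vcf bt2_hc.vcf bt2_vs.vcf
#> bwa_hc.vcf       1.00       0.47       0.50       0.44
#> bwa_vs.vcf       0.47       1.00       0.43       0.56
#> bt2_hc.vcf       0.50       0.43       1.00       0.53
#> bt2_vs.vcf       0.44       0.56       0.53       1.00

golden <- file.path("demo", "golden.vcf.gz")
write_variants_vcf(intersection_all(callsets), golden)
benchmark_table(benchmark_many(callsets, read_golden(golden)))
#>                  name precision recall n_correct n_called n_golden
#> bwa_hc.vcf bwa_hc.vcf 0.3863636      1        17       44       17
#> bwa_vs.vcf bwa_vs.vcf 0.3953488      1        17       43       17
#> bt2_hc.vcf bt2_hc.vcf 0.4250000      1        17       40       17
#> bt2_vs.vcf bt2_vs.vcf 0.4473684      1        17       38       17
```

The Jaccard matrix shows every pairwise overlap after PASS filtering.
Because the golden set here is the intersection of all four files it is
a subset of each of them, so every recall is exactly 1 and precision
ranks the files by how much they call beyond the consensus — the
smallest call set (`bt2_vs`, 38 PASS variants) is closest to it.

The same analysis runs from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/vcfcompare.R", package = "vcfcompare"))')
Rscript "$CLI" venn --compare demo/*.vcf --pass-only --out results/
Rscript "$CLI" pr --compare demo/*.vcf --golden demo/golden.vcf.gz \
    --pass-only --out results/
```

Subcommands `summary`, `venn`, `clustergram`, `pr` and `filter` expose
the full pipeline (`--metadata`, `--group-by`, `--combine`,
`--region-mode`, `--vtype`, `--chrom`, `--color-by`, `--shape-by`,
`--pseudo-venn`, ...); exit codes are 0 on success, 1 on input error, 2
on usage error.

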