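---
title: "Methods: exact-match comparison and benchmarking of VCF call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-match comparison and benchmarking of VCF call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfcompare)
```

## The comparison model

`vcfcompare` compares VCF files as sets of exact-match variant
identities. Each record contributes the key *(CHROM, POS, REF, ALT)*;
equality is component-wise string/integer equality, with exactly two
normalizations applied on load:

* REF and ALT are uppercased (case carries no meaning in these columns);
* multi-allelic records are split, one key per alternate allele, each
  inheriting the record's FILTER value.

Nothing else is normalized. In particular chromosome names are matched
verbatim (`"chr1"` and `"1"` are different chromosomes — the pipeline
warns when the compare set shares no chromosome name with the golden or
region sets, since that almost always means a naming-convention
mismatch), and no left-alignment or decomposition of indels is
attempted: two representations of the same underlying variation are
treated as distinct. That is the model's main assumption and its main
limitation; it makes every downstream quantity a pure set statistic, and
it means results on indel-heavy data depend on the callers having
normalized consistently.

Duplicate keys within one file are collapsed (the first record's FILTER
wins), so a "call set" is genuinely a set and counts are counts of
unique variants.

## Filters

Filters are pure subset operations, applied by the pipeline in a fixed
order: FILTER status, then genomic regions, then chromosome and variant
type. Each is idempotent, so the order only matters between stages, not
within repetitions.

**PASS.** Only the literal FILTER string `PASS` counts as passing;
`"."`, the empty string and caller-specific codes are all non-PASS.

**Regions.** BED intervals are 0-based half-open `[start, end)`, VCF
positions 1-based, so a variant at position $p$ is inside an interval
iff $p - 1 \in [start, end)$, equivalently $start < p \le end$. Only
POS — the variant's anchor base — is tested, not the full REF span; a
spanning deletion is classified by where it starts. This is a
convention, fixed and tested at the boundaries, chosen because it needs
no allele interpretation.

Two implementations exist on purpose. The naive one checks every
interval for every variant and serves as the oracle. The production one
exploits sortedness: per chromosome, variants (ascending POS) and
intervals (ascending start) are each walked exactly once, while a
running maximum of the ends of all intervals whose start has been passed
is maintained. A variant is covered iff that maximum exceeds its 0-based
position. The running maximum is what makes the sweep correct for
overlapping and nested intervals *without* merging them first. The two
implementations are property-tested for equality on randomized
instances, including empty region sets and adjacent/nested intervals.

**Type.** `snp` keeps 1 bp → 1 bp substitutions over {A, C, G, T};
`indel` keeps length-changing keys (which includes symbolic ALTs such as
`<DEL>`, since their textual length differs from REF's — they pass
through the parser verbatim). Balanced multi-base substitutions belong
to neither class and are dropped by both filters.

## Grouping

A metadata CSV (mandatory `FILENAME` column, unique values, covering the
compare set) assigns each file a tuple of property values; files sharing
a tuple in the chosen `group_by` columns form a group whose variants are
pooled by one of three rules: **union**, **intersection**, or
**majority** — membership in strictly more than half of the group's
members, so a 2-of-4 tie is excluded. These satisfy, and the tests
assert, intersection ⊆ majority ⊆ union, and all three coincide for
singleton groups. Groups are emitted ordered by their key tuples (the
source order of files carries no meaning), labels join the chosen label
columns' values with `" & "`, and pooled sets carry no FILTER status
because grouping runs after PASS filtering. Label collisions after
column subsetting are allowed but warned about.

## Overlap accounting and similarity

`venn_tally()` assigns each variant of the union of $k$ sets
(2 ≤ k ≤ 6) to exactly one of the $2^k - 1$ membership patterns,
encoded as bitmask strings over the ordered set names; counts therefore
sum to the union size and percentages to 1. The figure renderer draws
circles (k ≤ 3) or the classic rotated-ellipse layouts (k = 4, 5); for
k = 6 it uses a cyclic ring of circles — the arrangement commonly called
a pseudo-Venn — whether or not the pseudo-Venn option is set, because no
arrangement of six convex shapes realizes all 63 regions legibly. Region
labels (count and percentage) are placed at centroids found numerically:
the canvas is rasterized on a 301 × 301 grid, each grid point classified
by shape membership, and each realized pattern labeled at its points'
mean. Patterns the layout cannot realize are absent from the figure but
never from the CSV sibling, which always carries the full tally; the
figure is a view, the CSV is the record.

Pairwise similarity is the Jaccard index
$J(A,B) = |A \cap B| / |A \cup B|$. (Some tools label this quantity a
"Jaccard distance"; the formula is a similarity, and outputs here say
so.) It is undefined when both sets are empty, and the matrix
constructor refuses empty sets by name rather than emitting NaN.
Clustergram ordering uses agglomerative clustering on the distance
$1 - J$ with **average linkage** (UPGMA) via `stats::hclust`. Average
linkage is a deliberate, documented fixture — the merge order of
single/complete linkage is more sensitive to single shared variants —
and ties break deterministically by input order, so the leaf order is
reproducible. The same order is applied to rows and columns.

## Benchmarking

Against a golden set $G$ (one or more VCFs pooled by union — pooling
method for multiple golden files is a package decision, as is the choice
to filter only the compare set, never the golden set):

$$\mathrm{precision} = \frac{|C \cap G|}{|C|} \qquad
  \mathrm{recall} = \frac{|C \cap G|}{|G|}$$

with exact-match intersection. Empty $C$ or $G$ raises an error;
division by zero is never silently returned. Results carry
`n_correct`, `n_called`, `n_golden` alongside the ratios so exported
CSVs are self-auditing. Useful consequences, all property-tested: a
compare set that is a subset of $G$ has precision 1; one that is a
superset has recall 1 — in particular, when the golden set is the
intersection of all compare files, every file's recall is exactly 1;
union-pooling a group can only keep or raise recall relative to its
members, intersection-pooling only keep or lower it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_size` / `--max-file-size` | 200 MB | per-file size cap at load (bytes) |
| `combine` | union | group pooling rule |
| `region_mode` | none | `inside` / `outside` region filtering |
| `font_size` | 12 pt | base font of all figures |
| `colormap` | viridis | clustergram palette (`magma`, `heat`, `blue-red`) |
| `pseudo_venn` | off | cyclic 6-set layout flag (6 sets only) |

A small INI config (`--config`) can preset `font_size` and
`preset_regions_dir`, the directory whose `*.bed` files are addressable
as `--preset-region NAME`; command-line flags override config values.

## The synthetic-data generator

`overlap_design()` + `synth_vcfs()` generate compare sets by *overlap
pattern*: the design states how many distinct variants belong to each
membership pattern, keys are drawn without replacement from (chrom ∈
chr1..chr3, pos ∈ 1..10⁶, ref ≠ alt ∈ {A,C,G,T}) — distinctness is
guaranteed, so the generated files' Venn tally equals the design exactly
— and a `filter_mix` fraction per file marks `floor(n · f)` variants
non-PASS. Everything is deterministic under the design seed, to the
byte, and a manifest of every file's exact keys and FILTER assignments
is returned so tests can derive expected values for any downstream
statistic in closed form, independently of the readers. `synth_bed()`
likewise returns the exact covered positions of its intervals, and
`synth_metadata()` writes cycling property columns.

The generator emulates overlap structure only. It does not emulate
allele-frequency spectra, error models, genotype fields, real indel
representation ambiguity, or realistic chromosome structure — so
passing tests demonstrate the set algebra, parsing and accounting are
correct, not that any particular caller benchmark on real data would be
reproduced. Sizes used in the test suite are deliberately small
(tens of variants per file, ≤ 1000 random instances per property), which
exercises every code path and boundary; scale is limited only by memory
for the key vectors.

## Degenerate inputs and edge policies

* Header-only VCF → empty call set; empty golden path list → empty
  golden set (benchmarking then errors).
* Zip archives must contain exactly one member; compression is detected
  from magic bytes, not extensions.
* Empty region set: `inside` keeps nothing, `outside` keeps everything.
* Count-table ties keep input order (stable sort); pivot cells with no
  matching group are `NA`; a pivot cell matched by more than one group
  (possible when grouping used extra columns) is an error rather than a
  silent sum.
* All output ordering (variants in VCFs, groups, pattern lists) is
  deterministic under C collation, so identical requests produce
  byte-identical CSVs.

## Known limitations

Exact-match identity (no variant normalization, no distance-tolerant or
haplotype-aware matching), no genotype-aware comparison, no INFO-based
filtering, and figure export is PNG-only. These are boundaries of the
comparison model, not of the implementation.
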