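---
title: "Methods: hybrid (CLASH) record analysis with hybtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid (CLASH) record analysis with hybtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybtools)
```

## Background

CLASH-family experiments (CLASH, qCLASH, CLEAR-CLIP, chimeric e-CLIP)
ligate a microRNA to the target RNA it is bound to, in situ, before
sequencing. Each resulting read is a *hybrid* (chimera): two RNA segments
on one read, typically an 18-22 nt miRNA joined to a fragment of its
target. Hybrid callers emit these as tab-delimited *hyb* records — read
id, read sequence, an optional folding energy, and six alignment fields
per segment (reference id, read span, reference span, score), plus an
optional `key=value;...` flags column carrying annotations. Predicted
intramolecular secondary structure for each hybrid is usually carried
alongside in 3-line Vienna dot-bracket records.

`hybtools` covers the post-calling stage of such data: validation,
annotation, filtration, and descriptive analysis, with the matching
command-line tools and a seeded synthetic-data generator so every
behaviour can be exercised against known ground truth.

## The record model

A `hyb_record` holds one chimeric read with two `seg_info` segments and
an insertion-ordered flag table. Conventions the whole package relies
on:

* **Coordinates are 1-based inclusive**, in both read space and
  reference space, matching the upstream convention for hyb output.
* **seg1 is the 5' segment** (smaller read start). Files violating this
  are still parsed in file order; `check_hyb()` reports a `seg-order`
  warning rather than rejecting them, because upstream tools vary and
  QC should surface, not hide, such records. Overlapping read spans are
  likewise legal (ligation chimeras can be called with overlap) and
  warned about, not refused.
* **miRNA placement** (`miRNA_seg` flag) is one of `5p`, `3p`, `B`
  (both segments miRNA-typed), `N` (neither), `U` (a type annotation is
  missing). A segment counts as miRNA when its type string is a member
  of a configurable set, `{"miRNA", "microRNA"}` by default,
  case-sensitively — reference libraries are case-stable, and case
  folding would mask data errors.
* **Counting is explicit.** Every analysis weights records under a
  stated mode — `record` (1 each), `read_count`, or `count_total`
  (flag values) — rather than a silent fallback chain, so aggregated
  results are reproducible from the stated mode alone. A missing count
  flag falls back to 1; a present but non-positive one is an error.

## File dialects and fidelity

The hyb dialect is 15 fixed tab-separated columns plus the optional
flags column; `"."` marks a missing energy, reference coordinate, or
score. Parsed records retain the original textual tokens of the energy
and score fields, so records that pass through unmodified round-trip
**byte-exactly** — a property QC diffing depends on, and one the test
suite asserts on 1000-record generated files. Numeric tokens must match
`[+-]?digits(.digits)?([eE][+-]?digits)?`; anything else (locale commas,
stray characters) is a parse error to be triaged, never guessed at.
Gzip input is auto-detected from magic bytes. Comment (`#`) and blank
lines are tolerated on read and never written.

Vienna records are strictly 3-line (header, sequence, dot-bracket with
optional trailing `(energy)`); multi-structure records and pseudoknot
alphabets are rejected. Dot-brackets must be balanced and equal in
length to their sequence. Energy is written back as `%.1f` (the common
folder output style) unless the original token is unchanged.

## Merging hyb and fold records

Correspondence between a hyb file and its fold file is **positional**
(k-th record with k-th record), as produced by the upstream pipelines,
with id equality as an additional default check; id-keyed joining is
deliberately out of scope to keep the merge single-pass. Sequence
agreement is checked with T/U treated as equal (hyb files are
DNA-alphabet, folders emit RNA). `static` mode requires equal lengths at
offset zero; `dynamic` mode slides the fold sequence along the read and
takes the smallest offset within the mismatch budget — a fold sequence
longer than the read is a failure, not a reverse search. Failures are
values: under `warn_skip` they are counted in the merge statistics,
under `raise` the first failure aborts naming both ids and the pair
index.

## Segment typing and annotation

Classification is identifier-driven (no sequence alignment), via a
user-selectable method:

* `hyb_split` — split the reference id on `_` and take the **last**
  field, the layout of Hyb-style `gene_transcript_name_type`
  identifiers; the position and separator are configurable for other
  layouts.
* `string_match` — ordered `(kind, pattern, type)` rules, first match
  wins, in file order; kinds are `prefix`, `suffix`, `contains`,
  `full`.
* `id_map` — exact CSV lookup; duplicate keys are a load-time error
  because silent override hides data bugs.
* `callable` — any user function.

Raw types pass through an alias table (shipping with
`microRNA -> miRNA`; application is idempotent) so downstream analyses
see one canonical miRNA spelling. Unresolved identifiers are a distinct
value: policy (`"unknown"` vs error) is applied at annotation time, and
re-annotation overwrites prior type flags to support iterative
workflows.

## Filtration semantics

A filter spec is a non-empty set of predicate atoms over types,
placements, identifiers, flags, energies, and counts, combined with
`all` or `any`, under `include` or `exclude` polarity. Exclude is the
exact negation of include, so the two partition any input with order
preserved — a property tested over randomized specs. Predicates over a
missing flag or absent energy never error; they simply do not match
(strict workflows should run checking and annotation first). On the
command line, repeated `--include`/`--exclude` atoms compose with
excludes applied after includes.

## The five analyses

All enabled analyses run in one pass while records are added to the
accumulator. Records lacking what an analysis needs are tallied as
skipped for that analysis only. Finalized counter tables sort by
descending count with lexicographic tie-breaks, making results
deterministic and permutation-invariant.

* **energy** — histogram (default 1.0 kcal/mol bins spanning the
  observed range) plus weighted mean, min, max, n.
* **type** — marginals over `seg1_type`/`seg2_type` and the
  **unordered** type pair, with the miRNA member listed first when
  present (pair orientation is biologically arbitrary here).
* **mirna** — placement distribution and miRNA/target type pairs.
* **target** — per-miRNA target counters with totals and unique-target
  counts.
* **fold** — the per-nucleotide binding profile and the fold-energy
  distribution.

"Bound" at a miRNA position means the dot-bracket character under that
nucleotide is `(` or `)`; wobble or mismatch detail is not recoverable
from dot-bracket notation. The profile is indexed 5'-to-3' of the
miRNA regardless of placement. Because a published normalization for
such profiles is ambiguous (per-record vs read-count weighting; miRNAs
of unequal length thin out the tail positions), the profile table always
reports **both** weightings with their per-position denominators, and
positions with a zero denominator are reported empty rather than as 0.
`B`-placement records are excluded from target and fold analyses by
default (counted under `B` in the placement table); `both_as_seg1 =
TRUE` opts into treating their 5' segment as the miRNA.

## The synthetic-data generator

`generate_fixture()` emulates a qCLASH-like dataset: pools of miRNAs
(18-22 nt, four-part `_microRNA` identifiers) and targets (20-40 nt,
typed identifiers), read sequences formed by segment concatenation, and
a duplex model that marks a contiguous block of `b` miRNA nucleotides
(drawn uniformly from 4-10) as paired, encoded in a balanced
dot-bracket. Pseudo-energy is `-0.5 b` plus Uniform(-0.5, 0.5) noise —
a deliberately synthetic model that exists to test plumbing and
weighted statistics, not thermodynamics. `count_total` is
1 + Geometric(0.5). Defaults: target biotypes 60% mRNA / 30% lncRNA /
10% rRNA, placements 70% 5p / 20% 3p / 5% B / 5% N — the 5' dominance
reflects ligation-order bias in miRNA-directed protocols; all mixtures
are configurable. One seeded stream drives every choice, so a single
integer reproduces a dataset byte-for-byte, and a ground-truth table
(types, placement, counts, bound vectors, energy, injected mismatches)
is emitted with the files.

What the generator does **not** emulate: sequencing errors, adapters,
PCR duplicates, realistic folding energetics, multi-way chimeras, or
genomic target-region structure. Passing closed-loop tests therefore
demonstrates that the toolkit's bookkeeping is exact, not that it is
robust to artifacts absent from the model.

## Numerical and degenerate-input choices

* Dynamic fold matching breaks ties by smallest offset.
* Histogram bin edges are multiples of the bin width covering the
  observed range; a degenerate single-value range gets one bin.
* Empty accumulators finalize to empty tables; plotting an empty result
  warns and writes nothing.
* Flag keys are unique, insertion-ordered, forbidden to contain tab,
  newline, semicolon (and `=` in keys); a trailing `;` is accepted on
  read, never written.
* Exit codes: 0 success, 1 usage/configuration error, 2 data error.
  Output files are never modified in place; names derive from the input
  stem plus a settable suffix.

## Problem sizes

The shipped verification uses 1000-record datasets for format
round-trip and ground-truth recovery, 500 for the binding-profile
oracle comparison, 400 (5% defect rate) for merge robustness, 200
records x 50 random specs for filter partitioning, and 150 for
CLI/API equivalence — sizes at which every property is exact and the
whole suite runs in well under a minute.

## Limitations

Classification is identifier-driven only; no bundled reference
database; no genomic re-annotation of target regions (`target_reg` is
carried opaquely); no statistical testing of enrichment or differential
targeting — the analyses are descriptive. Files are processed in
memory, which is comfortable for desk-scale record sets but not tuned
for hundreds of millions of records.
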