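---
title: "Methods: antisense transcript discovery, classification and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antisense transcript discovery, classification and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind natkit: what each step computes,
why the defaults are what they are, and where the edges of the method lie.
All code chunks are illustrative (not evaluated here); the package's test
suite and `scripts/acceptance.R` are the executable record of its behaviour.

## The biological model

A *natural antisense transcript* (NAT) is an RNA transcribed from the strand
opposite a gene of interest, at the same genomic locus. We restrict
attention to *noncoding* antisense partners: transcripts with no annotated
CDS and a noncoding biotype. The interesting axes for such a pair are

* **where** the antisense RNA overlaps its sense partner — shared exonic
  sequence, intronic gene body only, or a head-to-head promoter
  arrangement — because the overlap architecture constrains both the
  plausible regulatory mechanism and the design of strand-safe assays;
* **where in the cell** the antisense RNA resides — noncoding antisense RNAs
  are frequently retained in the nucleoplasm or on chromatin;
* **whether** sense and antisense expression co-vary across tissues or
  sample groups (concordant, discordant, or indeterminate).

natkit operationalises each axis as a deterministic computation over a GTF
annotation plus tabular expression inputs.

## Coordinates and the span-string format

Internally every interval is **0-based, half-open** `[start, end)`; widths
are `end - start` and abutting intervals share no base. GTF input/output
converts to/from the standard 1-based inclusive convention at the boundary,
and BED output is natively 0-based half-open. This single internal
convention removes the classic off-by-one family of bugs from interval
arithmetic; the merge/intersect/subtract primitives themselves are delegated
to IRanges.

Locus coordinates are printed in **transcription direction** as
`chrom:from-to,strand` — a minus-strand locus prints its larger coordinate
first (`X:47765952-47764918,-1`). `parse_span_string()` takes the two
integers verbatim as half-open boundaries and normalises so `start < end`;
both the en-dash and ASCII hyphen separators are accepted.

## Gene models and the promoter window

`build_gene_models()` merges all isoforms of a query gene: the exon union is
the interval-merge of every isoform's exons, the span runs from the first to
the last exonic base, and the promoter is a fixed window upstream of the
transcription start (before `span.start` on `+`, after `span.end` on `-`,
clamped at zero). Gene symbols are matched case-insensitively and an alias
map can be supplied; genes whose transcripts disagree on chromosome or
strand are reported as ambiguous rather than silently merged.

The default window of **1000 bp** is the conventional proximal-promoter
scale used for head-to-head antisense arrangements. It is a configurable
parameter (`nat_config(promoter_window = ...)`), not an estimate: there is
no attempt to infer the true promoter extent from data.

## Discovery and locus grouping

For each gene model, every transcript on the opposite strand whose span
intersects the gene span or promoter window is a candidate. Candidates
keep only noncoding transcripts. Coding status comes from the annotation
with the precedence **CDS features > biotype attribute > unknown**; a
transcript with a CDS is coding no matter what its biotype says. The
`strict` policy (default) also discards `unknown` transcripts — an
annotation-conservative choice that trades sensitivity for precision; the
`permissive` policy keeps them. Discarded unknowns are listed in the report
(`excluded_unknown`) so the cost of the policy is visible. For AceView-style
input, which lacks a dedicated biotype key, the same attribute patterns are
matched against whatever attributes are present, so CDS evidence is
typically what decides.

Surviving transcripts are grouped into **antisense loci** by single-linkage
clustering on exonic overlap: two transcripts on the same strand and
chromosome belong to one locus if any exons share at least one base,
directly or through a chain of others. Single linkage is the right closure
for "these fragments are pieces of one transcriptional unit"; its known
failure mode (chaining across unrelated units that happen to touch) is
accepted and documented rather than patched with ad-hoc distance cutoffs.
The implementation is a union–find over IRanges overlap hits; the test
suite checks it against explicit graph components computed with igraph.

A locus overlapping several query genes is counted once in `n_nat_loci` but
forms one pair per gene, so per-gene classifications remain independent.

## Overlap classification

Each (gene, locus) pair is tested against the sense exon union, span and
promoter window, using the antisense locus's exon union (not its span):

* `exonic` — at least `min_overlap` bases (default 1) of antisense exon
  intersect sense exons;
* `intronic` — antisense exons intersect the span but **no** sense exon;
  exonic and intronic are mutually exclusive by construction, with exonic
  dominating;
* `promoter` — antisense exons intersect the promoter window; this flag is
  additive.

This yields exactly five labels: `exonic`, `intronic`, `promoter`,
`exonic; promoter`, `intronic; promoter`. The default `min_overlap = 1`
makes the classifier a pure topology statement; raising it is a stringency
knob, not a correction for alignment noise (the inputs are annotations, not
reads).

## Assay-region proposal

Validating an antisense RNA by qPCR requires amplicons that cannot be
explained by the sense transcript or by genomic DNA. Candidate regions are
ranked by kind:

1. `SPLICE_JUNCTION` — an exon–exon junction unique to the antisense
   transcript. A junction is a property of two exons, but a region must be a
   single interval inside the antisense exon union, so the region is
   anchored in the terminal `min_length` bases of the upstream flanking exon
   and the flanking pair is carried in the `junction_*` fields. Junction
   amplicons distinguish spliced RNA from genomic DNA, hence neither
   strand-specific chemistry nor a no-RT control is strictly required.
2. `NONOVERLAP_EXON` — antisense exon sequence outside the sense gene's
   exons, span and promoter.
3. `SENSE_INTRON_OVERLAP` — antisense exon over sense intron: detectable,
   but requires strand-specific reverse transcription.
4. `PROMOTER_OVERLAP` — antisense exon inside the promoter window; also
   strand-specific.

Non-junction regions are computed by subtracting the sense exon union from
the antisense exon union and then splitting the remainder at every span and
promoter boundary, so each reported region is a maximal interval of a single
kind (the span and the promoter are disjoint by construction, so the kind is
well defined per base). Pieces shorter than `min_assay_length` (default 60,
a practical lower bound for a qPCR amplicon) are dropped. All non-junction
kinds require a no-RT control. `select_assay_region()` orders by kind rank,
then width (descending), then coordinates — a total order, so selection is
deterministic and permutation-invariant. A pair whose antisense exons lie
entirely within sense exons has no safe region; this is reported as a
diagnostic, not an error, because it is a real and informative outcome for
fully exonic-overlap NATs.

## Locus quantification and localization

Fragment-level records (`locus_id`, `class_code`, `compartment`, `fpkm`)
are filtered to exclude class codes that indicate intronic or pre-mRNA
signal (defaults `i` and `e`); unknown codes are kept with a warning rather
than silently dropped, because an unrecognised code is more likely a new
assembler version than noise. FPKM is then summed per locus and compartment
with zero-filling, so total FPKM is conserved exactly by aggregation (the
test suite requires agreement to 1e-9 relative). `localization_profile()`
adds per-compartment fractions and the dominant compartment; ties go to the
first compartment in the configured order (default cytoplasm, nucleoplasm,
chromatin), and a locus with zero total signal has an undefined profile.

## qPCR statistics

* **Relative expression** is `efficiency^-(meanCt_target - meanCt_ref)` per
  sample, with replicate Ct values averaged *before* differencing and a
  default reference of PGK1 at efficiency 2. A sample with no finite
  replicate for the target (or reference) is a non-detect and yields `NA`
  with an explicit reason string.
* **Regional comparison** is fixed-effects one-way ANOVA with Tukey HSD
  post-hoc contrasts (`stats::aov` + `TukeyHSD`); two-sample comparisons use
  the equal-variance Student's t test. Degenerate inputs follow explicit
  conventions: zero total sum of squares gives F = 0, p = 1; zero pooled
  variance with equal means gives t = 0, p = 1, and with unequal means
  t = ±Inf, p = 0. These conventions make pipelines total functions rather
  than branching on exceptions.
* **Sense–antisense correlation** is the Pearson product-moment correlation
  with its standard t-based p-value; zero-variance input returns `NA` with a
  reason.
* **Concordance** compares the arg-max group of the sense and antisense
  profiles, optionally gated by the correlation sign at threshold
  `concordance_tau` (default 0.3): matching maxima with r > τ is
  `concordant`, mismatching maxima with r < −τ (or no r supplied) is
  `discordant`, and flat profiles or conflicting evidence are
  `indeterminate`.

All of these delegate the numerics to the corresponding `stats` functions;
the test suite verifies them against hand-computed sums of squares and
closed forms, checks F = t² for two groups, confirms Tukey-adjusted p-values
never fall below raw pairwise p-values, and calibrates type-I error by Monte
Carlo (10,000 null replicates per test, required inside 0.05 ± 0.01) along
with power for a 2-Ct regional effect at replicate SD 0.3.

## The synthetic generators

`simulate_annotation()` plants a configurable mix of antisense loci of every
class against template two/three-exon coding genes, one class at most once
per gene, using geometry chosen so that planted loci on the same gene can
never merge into one locus (the per-class slots are pairwise disjoint).
Optional decoys — a same-strand noncoding RNA, an opposite-strand *coding*
transcript, and a distant noncoding RNA — exercise the filters that a real
annotation would. `simulate_fragment_table()` draws fragment FPKM around
compartment weights with multiplicative lognormal noise (`sdlog = 0.25`,
mean-one parameterisation) and marks a fraction (default 0.2) with excluded
class codes. `simulate_ct_table()` draws replicate Ct values around group
means with normal noise (SD 0.3) for groups of 9/9/7 samples and a
reference target at Ct 20 — sizes and noise chosen to mimic a small
three-region qPCR panel.

These generators are deliberately stylised: exon counts are tiny, intergenic
spacing is uniform, FPKM noise ignores length/GC effects, and Ct noise is
homoscedastic. They are fixtures for verifying the *pipeline's* correctness
(known truth in, known truth out), not simulations of a transcriptome. The
defaults are part of the test contract and are not tuned against outcomes.

## Numerical and design choices

* Interval arithmetic via IRanges; union–find for grouping; `stats::aov`,
  `TukeyHSD`, `t.test`, `cor.test` for the statistics. The package authors
  the domain logic and delegates the established numerics.
* Every independently checkable step has a second, structurally different
  route in the tests: per-base integer sets for intervals, igraph components
  for grouping, hand sums of squares for ANOVA. Implementation and oracle
  never share code.
* All public entry points are deterministic given inputs and configuration;
  generator seeds are explicit arguments, and identical seeds reproduce
  files byte for byte.
* Problem sizes in tests and the acceptance script (tens of genes, hundreds
  of transcripts) are chosen for oracle tractability (the brute-force
  rediscovery is O(n²) on per-base sets), not as a statement about scaling;
  the implementation itself uses interval trees and scales far beyond that.

## Limitations

* Discovery is annotation-driven: an antisense transcript absent from the
  GTF is invisible, and coding-status errors in the annotation propagate.
* The promoter is a fixed-width window, not an inferred regulatory element.
* Single-linkage grouping can chain distinct units that share a single
  exonic base.
* The `strict` policy discards unannotated (`unknown`) transcripts, which
  is conservative for noisy annotations; use `permissive` and inspect
  `excluded_unknown` when sensitivity matters.
* The statistics layer assumes approximately normal within-group ΔCt and
  equal variances (classical qPCR practice); it performs no multiple-testing
  correction across targets, only across Tukey contrasts within a target.
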