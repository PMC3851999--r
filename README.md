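# natkit

Tools for discovering and characterising noncoding **natural antisense
transcripts (NATs)** that overlap a set of query genes — for example
candidate genes for a neurodevelopmental disorder.

Many protein-coding genes are partnered by a long noncoding RNA transcribed
from the opposite strand of the same locus. Such sense–antisense pairs can
share exonic sequence, overlap only intronic gene body, or face each other
head-to-head across a promoter, and the antisense partner is often enriched
in the nucleus (nucleoplasm or chromatin) rather than the cytoplasm. natkit
implements the complete computational workflow for a study of such pairs:

1. **Annotation parsing** — `read_gtf()` reads GTF transcript annotation
   (Ensembl-style or AceView-style attributes), records per-line parse
   errors, and assigns each transcript a coding status from its CDS features
   and/or biotype attributes (CDS evidence wins over biotype; transcripts
   with neither are `unknown`).
2. **Gene models** — `build_gene_models()` merges all isoforms of each query
   gene into an exon union, a genomic span, and a strand-aware promoter
   window (default 1000 bp upstream of the transcription start).
3. **Discovery** — `discover_nats()` scans for opposite-strand transcripts
   overlapping the span or promoter, drops coding transcripts (policy
   `strict` also drops `unknown`; `permissive` keeps them), groups the
   survivors into **antisense loci** by single-linkage exonic overlap
   (≥ 1 bp), and classifies each sense–locus pair.
4. **Classification** — `classify_overlap()` assigns `exonic` (antisense
   exon overlaps a sense exon) or `intronic` (gene-body overlap without any
   exonic overlap — the two are mutually exclusive), plus an additive
   `promoter` flag, yielding the five labels `exonic`, `intronic`,
   `promoter`, `exonic; promoter`, `intronic; promoter`.
5. **Assay design** — `enumerate_assay_regions()` proposes strand-safe qPCR
   target regions inside the antisense exon union, preferring splice
   junctions, then antisense exon sequence outside the sense gene, then
   intron- or promoter-overlapping sequence (which require strand-specific
   chemistry); `select_assay_region()` picks the best one deterministically.
6. **Localization** — `aggregate_locus_fpkm()` sums assembled-fragment FPKM
   per locus and subcellular compartment (cytoplasm / nucleoplasm /
   chromatin) after `filter_fragments()` removes intronic/pre-mRNA class
   codes, and `localization_profile()` derives compartment fractions and the
   dominant compartment.
7. **qPCR statistics** — `relative_expression()` computes
   2^−ΔCt-style relative expression against a reference gene (default
   PGK1), `region_comparison()` runs one-way ANOVA with Tukey HSD across
   sample groups (e.g. brain regions), `two_group_test()` is the equal-
   variance Student's t test, `sense_antisense_correlation()` the Pearson
   correlation, and `concordance_label()` summarises whether sense and
   antisense share their regional expression pattern.
8. **Simulation** — `simulate_annotation()`, `simulate_fragment_table()` and
   `simulate_ct_table()` generate seeded synthetic fixtures with known truth
   tables, used throughout the test suite.

Genome intervals are handled internally as 0-based half-open; GTF input and
output use the standard 1-based inclusive convention. Locus coordinates are
printed in transcription direction as `chrom:from-to,strand` (e.g.
`X:47765952-47764918,-1` for a minus-strand locus); `parse_span_string()`
and `format_span_string()` convert both ways.

## Quick start

```r
library(natkit)

# a seeded synthetic annotation with planted antisense loci of every class
sim <- simulate_annotation(n_genes = 6, seed = 42)
ann <- read_gtf(text = sim$gtf)
ann
#> nat_annotation: 30 transcripts, 24 genes (ensembl dialect)
#>   coding status: coding=16, noncoding=14

rep <- discover_nats(ann, sim$gene_symbols)
rep
#> nat_report: 5/6 queried genes have >=1 antisense locus; 8 loci, 8 pairs
#>   mean loci per positive gene: 1.60
#>   overlap classes: exonic=2, intronic=2, promoter=2, exonic; promoter=1, intronic; promoter=1

rep$pairs[, c("gene_symbol", "locus_id", "coords", "label")]
#>   gene_symbol locus_id              coords              label
#> 1     GENE001 NATL0001 chr1:19300-19100,-1           promoter
#> 2     GENE001 NATL0002 chr1:20600-20400,-1           intronic
#> 3     GENE002 NATL0005 chr2:21150-21050,-1             exonic
#> 4     GENE004 NATL0003 chr1:52380-51750,-1 intronic; promoter
#> 5     GENE004 NATL0004 chr1:52600-52400,-1           intronic
#> 6     GENE005 NATL0006  chr2:54300-54500,1           promoter
#> 7     GENE006 NATL0007  chr3:52050-54800,1   exonic; promoter
#> 8     GENE006 NATL0008  chr3:53050-53150,1             exonic

# strand-safe qPCR regions for the first pair
p <- rep$pairs[1, ]
enumerate_assay_regions(rep$models[[p$gene_symbol]], rep$loci[[p$locus_id]])
#>               kind chrom start   end strand width strand_specific_required
#> 1 PROMOTER_OVERLAP  chr1 19100 19300      -   200                     TRUE
#> ... (junction fields NA for non-junction regions)

# qPCR: a 2-Ct cerebellar effect, analysed across regions
csim <- simulate_ct_table(list(NAT1 = c(PFC = 26, STG = 26, CER = 24)),
                          seed = 42)
rel <- relative_expression(csim$ct)
region_comparison(rel$rel_expr, rel$group)
#> one-way ANOVA + Tukey HSD: statistic = 126.7, p = 8.48e-13
#> pairwise (Tukey-adjusted):
#>   contrast       diff       lwr       upr     p_adj
#> 1  PFC-CER -0.0501974 -0.059114 -0.041281 4.724e-12
#> 2  STG-CER -0.0496692 -0.058586 -0.040752 5.818e-12
#> 3  STG-PFC  0.0005283 -0.007813  0.008869 9.862e-01
```

## Command line

`inst/cli/natkit` (installed under `system.file("cli", "natkit", package =
"natkit")`) exposes the pipeline as subcommands:

```sh
natkit simulate --preset annotation --seed 31 --out-dir sim/
natkit discover --gtf sim/annotation.gtf --genes sim/genes.txt --out-dir out/
natkit classify --gtf sim/annotation.gtf --sense GENE003 \
       --antisense-span "chr1:52600-52400,-1"
natkit assay --gtf sim/annotation.gtf --genes sim/genes.txt --out-dir out/
natkit locus-quant --fragments fragments.tsv --out-dir out/
natkit stats --ct ct.tsv --out-dir out/
```

Options can also come from a JSON config file (`--config cfg.json`, written
by `write_config()`); explicit flags win over the file. Exit codes: 0
success, 1 usage error, 2 missing input file, 3 unparseable input.

## Testing

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "natkit", load_package = "installed")'
```

The suite checks every layer against independent oracles: discovery against
a brute-force O(n²) per-base-set rediscovery, locus grouping against
explicit graph components (igraph), assay regions against a per-base mask,
ANOVA/t/correlation against hand-computed sums of squares and closed forms,
and Monte-Carlo calibration of type-I error and power.

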