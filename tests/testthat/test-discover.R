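make_ann <- function(lines) read_gtf(text = lines)

# one plus-strand sense gene [100,400) with exons [100,200) and [300,400)
sense_lines <- c(
  gtf_line("chr1", "exon", 100, 200, "+", "SG", "SG.1"),
  gtf_line("chr1", "CDS", 100, 200, "+", "SG", "SG.1", frame = "0"),
  gtf_line("chr1", "exon", 300, 400, "+", "SG", "SG.1"),
  gtf_line("chr1", "CDS", 300, 400, "+", "SG", "SG.1", frame = "0"))

test_that("opposite-strand candidates come from span or promoter, never same strand/gene", {
  lines <- c(sense_lines,
    gtf_line("chr1", "exon", 150, 250, "-", "N1", "N1.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 150, 250, "+", "N2", "N2.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 50, 90, "-", "N3", "N3.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 5000, 5100, "-", "N4", "N4.1", biotype = "noncoding"),
    gtf_line("chr2", "exon", 150, 250, "-", "N5", "N5.1", biotype = "noncoding"))
  ann <- make_ann(lines)
  model <- build_gene_models(ann, "SG", promoter_window = 80)$models$SG
  cand <- find_antisense_candidates(model, ann)
  # N1 overlaps the span; N3 overlaps the promoter window [20,100)
  expect_setequal(cand, c("N1.1", "N3.1"))
})

test_that("the noncoding filter honours the coding-status policy", {
  expect_false(is_noncoding("coding", "strict"))
  expect_false(is_noncoding("coding", "permissive"))
  expect_true(is_noncoding("noncoding", "strict"))
  expect_false(is_noncoding("unknown", "strict"))
  expect_true(is_noncoding("unknown", "permissive"))
})

test_that("overlap classification separates exonic, intronic and promoter flags", {
  ann <- make_ann(sense_lines)
  model <- build_gene_models(ann, "SG", promoter_window = 80)$models$SG
  mk_locus <- function(starts, ends) structure(
    list(locus_id = "L", chrom = "chr1", strand = "-",
         exon_union = data.frame(start = starts, end = ends),
         span = c(min(starts), max(ends))), class = "antisense_locus")

  expect_equal(classify_overlap(model, mk_locus(150, 250))$flags, "exonic")
  # inside the intron [200,300): gene-body overlap without exon overlap
  expect_equal(classify_overlap(model, mk_locus(220, 280))$flags, "intronic")
  # promoter window is [20,100)
  expect_equal(classify_overlap(model, mk_locus(30, 90))$flags, "promoter")
  cls <- classify_overlap(model, mk_locus(c(50, 150), c(90, 250)))
  expect_equal(cls$flags, c("exonic", "promoter"))
  expect_equal(cls$label, "exonic; promoter")
  cls2 <- classify_overlap(model, mk_locus(c(50, 220), c(90, 280)))
  expect_equal(cls2$label, "intronic; promoter")
  # no overlap at all -> empty flags, label empty
  expect_length(classify_overlap(model, mk_locus(5000, 5100))$flags, 0L)
  # contract: same-strand input is a programming error
  bad <- mk_locus(150, 250); bad$strand <- "+"
  expect_error(classify_overlap(model, bad), "opposite strands")
})

test_that("single-linkage locus grouping matches the brute-force overlap graph", {
  lines <- c(
    gtf_line("chr1", "exon", 100, 200, "-", "A", "A.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 150, 300, "-", "B", "B.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 300, 400, "-", "C", "C.1", biotype = "noncoding"),
    gtf_line("chr1", "exon", 100, 200, "+", "D", "D.1", biotype = "noncoding"))
  ann <- make_ann(lines)
  loci <- group_into_loci(ann, c("A.1", "B.1", "C.1", "D.1"))
  parts <- lapply(loci, `[[`, "transcript_ids")
  # [100,200) and [150,300) chain; [300,400) only abuts (half-open: no overlap);
  # same coordinates on the opposite strand never merge
  expect_setequal(vapply(parts, paste, "", collapse = "+"),
                  c("A.1+B.1", "C.1", "D.1"))
  # locus ids are ordered by coordinate
  expect_equal(unname(vapply(loci, `[[`, "", "locus_id")),
               sprintf("NATL%04d", seq_along(loci)))
  expect_true(all(diff(vapply(loci, function(l) l$span[1], 0)) >= 0))

  # randomized fixture vs explicit graph components
  set.seed(99)
  rl <- character(0); ids <- character(0)
  for (i in 1:50) {
    s <- sample(0:3000, 1); w <- sample(50:400, 1)
    tid <- sprintf("R%02d.1", i); ids <- c(ids, tid)
    rl <- c(rl, gtf_line("chr1", "exon", s, s + w, "-", sprintf("R%02d", i),
                         tid, biotype = "noncoding"))
  }
  rann <- make_ann(rl)
  got <- lapply(group_into_loci(rann, ids), `[[`, "transcript_ids")
  comp <- oracle_components(rann, ids)
  want <- unname(lapply(split(ids, comp), sort))
  expect_setequal(vapply(got, paste, "", collapse = "+"),
                  vapply(want, paste, "", collapse = "+"))
})

test_that("discover_nats recovers the planted fixture truth exactly", {
  sim <- simulate_annotation(n_genes = 10, seed = 21)
  ann <- read_gtf(text = sim$gtf)
  rep <- discover_nats(ann, sim$gene_symbols)
  truth <- sim$truth$planted_pairs

  expect_equal(rep$n_genes_queried, 10L)
  expect_equal(rep$n_genes_with_nat, length(unique(truth$gene_symbol)))
  expect_equal(rep$n_nat_loci, nrow(truth))
  expect_equal(rep$mean_loci_per_positive_gene,
               nrow(truth) / length(unique(truth$gene_symbol)))
  got <- rep$pairs[order(rep$pairs$gene_symbol, rep$pairs$start),
                   c("gene_symbol", "label")]
  want <- truth[order(truth$gene_symbol, truth$start),
                c("gene_symbol", "label")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # histogram is per pair and reflects the planted class mix
  h <- class_histogram(rep)
  expect_equal(sum(h), nrow(rep$pairs))
  expect_equal(h[names(sim$truth$class_counts)],
               sim$truth$class_counts[names(sim$truth$class_counts)],
               ignore_attr = TRUE)
})

test_that("a coding-only opposite-strand transcript yields zero pairs", {
  lines <- c(sense_lines,
    gtf_line("chr1", "exon", 150, 250, "-", "C1", "C1.1"),
    gtf_line("chr1", "CDS", 150, 250, "-", "C1", "C1.1", frame = "0"))
  rep <- discover_nats(make_ann(lines), "SG")
  expect_equal(nrow(rep$pairs), 0L)
  expect_equal(rep$n_nat_loci, 0L)
  expect_true(is.na(rep$mean_loci_per_positive_gene))
})

test_that("unknown coding status is excluded under strict but kept under permissive", {
  lines <- c(sense_lines,
    gtf_line("chr1", "exon", 150, 250, "-", "U1", "U1.1"))
  ann <- make_ann(lines)
  strict <- discover_nats(ann, "SG", nat_config(coding_policy = "strict"))
  expect_equal(nrow(strict$pairs), 0L)
  expect_equal(strict$excluded_unknown, "U1.1")
  perm <- discover_nats(ann, "SG", nat_config(coding_policy = "permissive"))
  expect_equal(nrow(perm$pairs), 1L)
  expect_equal(perm$pairs$label, "exonic")
})

test_that("empty gene list and empty histogram behave", {
  ann <- make_ann(sense_lines)
  rep <- discover_nats(ann, character(0))
  expect_equal(rep$n_genes_queried, 0L)
  expect_equal(nrow(rep$pairs), 0L)
  expect_true(all(class_histogram(rep) == 0L))
})

test_that("identical inputs give byte-identical reports (determinism)", {
  sim <- simulate_annotation(n_genes = 8, seed = 5)
  ann <- read_gtf(text = sim$gtf)
  r1 <- discover_nats(ann, sim$gene_symbols)
  r2 <- discover_nats(ann, sim$gene_symbols)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r1, d1); write_report(r2, d2)
  for (f in c("pairs.tsv", "report.json", "loci.bed"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("a shared locus counts once in n_nat_loci but pairs with each gene", {
  # two plus-strand genes close together; one antisense transcript spans both
  lines <- c(
    gtf_line("chr1", "exon", 1000, 1400, "+", "GA", "GA.1"),
    gtf_line("chr1", "CDS", 1000, 1400, "+", "GA", "GA.1", frame = "0"),
    gtf_line("chr1", "exon", 2000, 2400, "+", "GB", "GB.1"),
    gtf_line("chr1", "CDS", 2000, 2400, "+", "GB", "GB.1", frame = "0"),
    gtf_line("chr1", "exon", 1200, 2200, "-", "N", "N.1",
             biotype = "noncoding"))
  rep <- discover_nats(make_ann(lines), c("GA", "GB"),
                       nat_config(promoter_window = 100))
  expect_equal(nrow(rep$pairs), 2L)
  expect_equal(rep$n_nat_loci, 1L)
  expect_equal(rep$n_genes_with_nat, 2L)
  expect_equal(sum(class_histogram(rep)), 2L)
})
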