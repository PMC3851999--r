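#' Seeded synthetic annotation with planted antisense loci
#'
#' Generates a GTF annotation of well-separated multi-isoform sense genes
#' plus planted opposite-strand noncoding transcripts whose geometry
#' guarantees a requested overlap class, and returns a machine-readable
#' truth table. Decoys exercise every filter: same-strand noncoding
#' transcripts (not antisense), opposite-strand *coding* transcripts
#' (filtered by the noncoding rule) and distant noncoding transcripts (no
#' overlap).
#'
#' Every sense gene has two isoforms sharing exon 1 and exon 3 of a
#' three-exon template (exon offsets 0-200, 1000-1200, 2000-2200 from the
#' gene start), so the merged exon cover has two introns; planted antisense
#' transcripts occupy disjoint per-class slots within one gene, so several
#' loci planted on one gene never merge. Each class may be planted at most
#' once per gene; a class count above `n_genes` is a generation error, as is
#' a promoter window under 100 bp (the promoter slots need room).
#'
#' @param n_genes Number of sense genes.
#' @param class_mix Named integer vector of planted locus counts per label
#'   (`exonic`, `intronic`, `promoter`, `exonic; promoter`,
#'   `intronic; promoter`).
#' @param promoter_window Promoter window (bp) the fixture is built for;
#'   must match the window used at discovery time. Must be >= 100.
#' @param seed Integer seed; identical seeds give byte-identical GTF text.
#' @param decoys Plant decoy transcripts (default TRUE).
#' @param n_chroms Number of chromosomes to spread genes over.
#' @return List: `gtf` (character vector of GTF lines), `gene_symbols`,
#'   `truth` (list with `planted_pairs` data.frame: gene_symbol,
#'   transcript_id, label; and `class_counts`).
#' @export
simulate_annotation <- function(n_genes = 10,
                                class_mix = c("exonic" = 2, "intronic" = 2,
                                              "promoter" = 2,
                                              "exonic; promoter" = 1,
                                              "intronic; promoter" = 1),
                                promoter_window = 1000, seed = 1,
                                decoys = TRUE, n_chroms = 3) {
  stopifnot(n_genes >= 1, all(class_mix >= 0))
  if (promoter_window < 100)
    stop("promoter_window below 100 bp leaves no room for promoter slots")
  bad <- setdiff(names(class_mix), LEGAL_LABELS)
  if (length(bad)) stop("illegal class labels: ", paste(bad, collapse = ", "))
  if (any(class_mix > n_genes))
    stop("cannot plant more loci of one class than there are genes")
  set.seed(seed)
  symbols <- sprintf("GENE%03d", seq_len(n_genes))
  chrom <- sprintf("chr%d", (seq_len(n_genes) - 1L) %% n_chroms + 1L)
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  gstart <- 20000 + (idx_on_chrom - 1L) * (30000 + 2 * promoter_window)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  lines <- character(0)
  emit <- function(chr, feat, s0, e0, std, attrs, frame = ".") {
    lines[[length(lines) + 1L]] <<- sprintf(
      "%s\tnatkit_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      chr, feat, as.integer(s0) + 1L, as.integer(e0), std, frame, attrs)
  }
  attrs_of <- function(gene, tx, biotype = NULL) {
    bt <- if (is.null(biotype)) ""
          else sprintf(' transcript_biotype "%s";', biotype)
    sprintf('gene_id "%s"; transcript_id "%s";%s', gene, tx, bt)
  }

  # sense genes: two coding isoforms over a fixed three-exon template
  sense_exons <- function(g) list(
    A = iv_df(g + c(0, 1000, 2000), g + c(200, 1200, 2200)),
    B = iv_df(g + c(0, 2000), g + c(200, 2200)))
  for (i in seq_len(n_genes)) {
    iso <- sense_exons(gstart[i])
    for (nm in names(iso)) {
      tid <- sprintf("%s.t%s", symbols[i], nm)
      a <- attrs_of(symbols[i], tid, "protein_coding")
      for (j in seq_len(nrow(iso[[nm]]))) {
        emit(chrom[i], "exon", iso[[nm]]$start[j], iso[[nm]]$end[j],
             strand[i], a)
        emit(chrom[i], "CDS", iso[[nm]]$start[j], iso[[nm]]$end[j],
             strand[i], a, frame = "0")
      }
    }
  }

  # promoter interval per gene (strand-aware), and planted-class slots
  prom <- function(i) {
    g <- gstart[i]
    if (strand[i] == "-") c(g + 2200, g + 2200 + promoter_window)
    else c(g - promoter_window, g)
  }
  prom_slot <- function(i, f0, f1) {
    p <- prom(i); w <- p[2] - p[1]
    c(floor(p[1] + f0 * w), floor(p[1] + f1 * w))
  }
  slot_exons <- function(i, label) {
    g <- gstart[i]
    switch(label,
      "exonic" = iv_df(g + 1050, g + 1150),
      "intronic" = iv_df(g + 400, g + 600),
      "promoter" = { s <- prom_slot(i, 0.10, 0.30); iv_df(s[1], s[2]) },
      "exonic; promoter" = {
        s <- prom_slot(i, 0.50, 0.60)
        iv_df(c(g + 50, s[1]), c(g + 150, s[2]))
      },
      "intronic; promoter" = {
        s <- prom_slot(i, 0.75, 0.85)
        iv_df(c(g + 300, s[1]), c(g + 380, s[2]))
      })
  }

  # assign planted loci: class c gets `class_mix[c]` distinct genes
  planted <- list()
  for (label in names(class_mix)) {
    k <- class_mix[[label]]
    if (k == 0) next
    genes <- sort(sample.int(n_genes, k))
    for (i in genes) {
      exd <- slot_exons(i, label)
      exd <- exd[order(exd$start), , drop = FALSE]
      tid <- sprintf("nat.%s.%s", symbols[i],
                     gsub("[^a-z]+", "", gsub("; ", "_", label)))
      opp <- if (strand[i] == "+") "-" else "+"
      a <- attrs_of(paste0("ng.", tid), tid, "noncoding")
      for (j in seq_len(nrow(exd)))
        emit(chrom[i], "exon", exd$start[j], exd$end[j], opp, a)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_symbol = symbols[i], transcript_id = tid, label = label,
        chrom = chrom[i], start = min(exd$start), end = max(exd$end),
        strand = opp, stringsAsFactors = FALSE)
    }
  }

  if (decoys) {
    for (i in seq_len(n_genes)) {
      g <- gstart[i]; opp <- if (strand[i] == "+") "-" else "+"
      # same-strand noncoding over an intron: not antisense, must be ignored
      if (stats::runif(1) < 0.7) {
        tid <- sprintf("dec.ss.%s", symbols[i])
        emit(chrom[i], "exon", g + 700, g + 900, strand[i],
             attrs_of(paste0("ng.", tid), tid, "noncoding"))
      }
      # opposite-strand coding transcript over a sense exon: filtered out
      if (stats::runif(1) < 0.7) {
        tid <- sprintf("dec.cod.%s", symbols[i])
        a <- attrs_of(paste0("cg.", tid), tid, "protein_coding")
        emit(chrom[i], "exon", g + 2050, g + 2150, opp, a)
        emit(chrom[i], "CDS", g + 2050, g + 2150, opp, a, frame = "0")
      }
      # distant opposite-strand noncoding: no overlap, must be ignored
      if (stats::runif(1) < 0.7) {
        tid <- sprintf("dec.far.%s", symbols[i])
        emit(chrom[i], "exon", g + 12000 + promoter_window,
             g + 12200 + promoter_window, opp,
             attrs_of(paste0("ng.", tid), tid, "noncoding"))
      }
    }
  }

  planted_pairs <- if (length(planted)) do.call(rbind, planted)
    else data.frame(gene_symbol = character(), transcript_id = character(),
                    label = character(), chrom = character(),
                    start = numeric(), end = numeric(), strand = character(),
                    stringsAsFactors = FALSE)
  list(gtf = unlist(lines),
       gene_symbols = symbols,
       truth = list(planted_pairs = planted_pairs,
                    class_counts = class_mix[class_mix > 0],
                    promoter_window = promoter_window))
}

#' Seeded synthetic fragment quantification table
#'
#' Draws per-fragment FPKM from a log-normal noise model around each locus x
#' compartment weight (expected compartment sum equals the weight), and
#' assigns a configurable fraction of fragments to excluded structural
#' classes (intronic `i` / pre-mRNA `e`), emulating a transcript-assembly
#' comparison table.
#'
#' @param loci Character vector of locus ids.
#' @param profiles Numeric matrix (loci x compartments) of expected
#'   compartment FPKM sums; rownames = loci, colnames = compartments.
#' @param n_fragments Fragments per locus x compartment (default 20).
#' @param intronic_rate Fraction of fragments given excluded class codes.
#' @param sdlog Log-normal noise sd on the log scale (default 0.25).
#' @param seed Integer seed.
#' @return List: `records` (fragment data.frame), `truth` (list with
#'   `expected_dominant`, per locus, from the weights with first-compartment
#'   tie-break).
#' @export
simulate_fragment_table <- function(loci, profiles, n_fragments = 20,
                                    intronic_rate = 0.2, sdlog = 0.25,
                                    seed = 1) {
  stopifnot(all(profiles >= 0), intronic_rate >= 0, intronic_rate <= 1,
            n_fragments >= 1)
  if (is.null(rownames(profiles))) rownames(profiles) <- loci
  comps <- colnames(profiles)
  set.seed(seed)
  rows <- list()
  for (l in loci) for (comp in comps) {
    w <- profiles[l, comp]
    fpkm <- (w / n_fragments) *
      stats::rlnorm(n_fragments, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    excluded <- stats::runif(n_fragments) < intronic_rate
    code <- ifelse(excluded, sample(c("i", "e"), n_fragments, replace = TRUE),
                   sample(c("=", "j"), n_fragments, replace = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_id = sprintf("frag.%s.%s.%03d", l, comp,
                            seq_len(n_fragments)),
      locus_id = l, class_code = code, compartment = comp, fpkm = fpkm,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows); rownames(records) <- NULL
  dominant <- apply(profiles[loci, , drop = FALSE], 1L, function(w)
    if (sum(w) == 0) NA_character_ else comps[which.max(w)])
  list(records = records,
       truth = list(expected_dominant = dominant, profiles = profiles,
                    intronic_rate = intronic_rate))
}

#' Seeded synthetic qPCR Ct table
#'
#' Emulates a multi-region qPCR study (default group sizes 9 PFC, 9 STG and
#' 7 cerebellum samples): each replicate Ct is the target's true group mean
#' plus normal noise, with the reference gene generated from its own mean in
#' every sample.
#'
#' @param effects Named list: target -> named numeric vector of true group
#'   mean Cts (names = groups).
#' @param group_n Named integer vector of samples per group
#'   (default `c(PFC = 9, STG = 9, CER = 7)`).
#' @param replicate_sd Technical replicate noise sd in cycles (default 0.3).
#' @param n_replicates Technical replicates per reaction (default 3).
#' @param reference Reference target name (default `"PGK1"`).
#' @param reference_mean True reference Ct (default 20).
#' @param seed Integer seed.
#' @return List: `ct` (long data.frame: sample, group, target, replicate,
#'   ct, nondetect), `truth` (the effect table).
#' @export
simulate_ct_table <- function(effects,
                              group_n = c(PFC = 9, STG = 9, CER = 7),
                              replicate_sd = 0.3, n_replicates = 3,
                              reference = "PGK1", reference_mean = 20,
                              seed = 1) {
  stopifnot(replicate_sd >= 0, n_replicates >= 1)
  groups <- names(group_n)
  for (t in names(effects))
    if (!setequal(names(effects[[t]]), groups))
      stop("effect table for '", t, "' does not cover the design groups")
  set.seed(seed)
  targets <- c(names(effects), reference)
  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    for (s in seq_len(group_n[[gi]])) {
      sid <- sprintf("%s_s%02d", grp, s)
      for (t in targets) {
        mu <- if (t == reference) reference_mean else effects[[t]][[grp]]
        cts <- mu + stats::rnorm(n_replicates, 0, replicate_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, group = grp, target = t,
          replicate = seq_len(n_replicates), ct = cts, nondetect = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  ct <- do.call(rbind, rows); rownames(ct) <- NULL
  list(ct = ct, truth = list(effects = effects, group_n = group_n,
                             replicate_sd = replicate_sd,
                             reference = reference,
                             reference_mean = reference_mean))
}

#' Write a simulated Ct table as TSV (readable by [read_ct_table()])
#' @param ct data.frame from [simulate_ct_table()]`$ct`.
#' @param file Output path.
#' @export
write_ct_table <- function(ct, file) {
  out <- ct[, c("sample", "group", "target", "replicate", "ct")]
  out$ct <- ifelse(is.na(out$ct), "ND", format(out$ct, digits = 10))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a simulated fragment table as TSV
#' @param records data.frame from [simulate_fragment_table()]`$records`.
#' @param file Output path.
#' @export
write_fragment_table <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
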