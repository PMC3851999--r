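# Brute-force oracles, deliberately independent of the package internals:
# interval arithmetic is done on explicit per-base integer sets and locus
# grouping on an explicit overlap graph (igraph when available, else a naive
# closure). Only used on small fixtures.

iv_bases <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  sort(unique(unlist(mapply(function(s, e) seq.int(s, e - 1L),
                            df$start, df$end, SIMPLIFY = FALSE))))
}

seq_bases <- function(lo, hi) if (hi > lo) seq.int(lo, hi - 1L) else integer(0)

# Independent gene-model construction from the raw exon table.
oracle_gene_model <- function(ann, symbol, promoter_window) {
  tx <- ann$transcripts[tolower(ann$transcripts$gene_id) == tolower(symbol), ]
  if (nrow(tx) == 0L) return(NULL)
  if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L)
    return("ambiguous")
  ex <- ann$exons[ann$exons$transcript_id %in% tx$transcript_id, ]
  bases <- iv_bases(ex)
  span <- c(min(bases), max(bases) + 1L)
  prom <- if (tx$strand[1] == "-") c(span[2], span[2] + promoter_window)
          else c(max(0, span[1] - promoter_window), span[1])
  list(symbol = symbol, chrom = tx$chrom[1], strand = tx$strand[1],
       exon_bases = bases, span = span,
       prom_bases = seq_bases(prom[1], prom[2]),
       gene_id = tx$gene_id[1])
}

# O(n^2) pairwise rediscovery of the full pipeline output.
oracle_discover <- function(ann, genes, promoter_window = 1000,
                            policy = "strict", min_overlap = 1) {
  tx <- ann$transcripts
  models <- list()
  for (sym in genes) {
    m <- oracle_gene_model(ann, sym, promoter_window)
    if (is.null(m) || identical(m, "ambiguous")) next
    models[[sym]] <- m
  }
  exon_bases_of <- function(tid)
    iv_bases(ann$exons[ann$exons$transcript_id == tid, ])
  nc_ok <- function(flag) flag == "noncoding" ||
    (flag == "unknown" && policy == "permissive")

  cand <- list()
  for (sym in names(models)) {
    m <- models[[sym]]
    lo <- min(m$span[1], min(c(m$prom_bases, m$span[1])))
    hi <- max(m$span[2], max(c(m$prom_bases + 1L, m$span[2])))
    opp <- if (m$strand == "+") "-" else "+"
    hits <- character(0)
    for (i in seq_len(nrow(tx))) {
      if (tx$chrom[i] != m$chrom || tx$strand[i] != opp) next
      if (tolower(tx$gene_id[i]) == tolower(m$gene_id)) next
      if (tx$start[i] < hi && tx$end[i] > lo) hits <- c(hits, tx$transcript_id[i])
    }
    cand[[sym]] <- hits[vapply(hits, function(t)
      nc_ok(tx$coding_flag[tx$transcript_id == t]), logical(1))]
  }
  all_nc <- unique(unlist(cand, use.names = FALSE))
  # locus partition: explicit overlap graph -> connected components
  comp <- oracle_components(ann, all_nc)
  groups <- split(all_nc, comp)
  ginfo <- lapply(groups, function(members) {
    b <- iv_bases(ann$exons[ann$exons$transcript_id %in% members, ])
    e1 <- ann$exons[ann$exons$transcript_id == members[1], ]
    list(members = sort(members), bases = b, chrom = e1$chrom[1],
         strand = e1$strand[1], start = min(b))
  })
  ord <- order(vapply(ginfo, `[[`, character(1), "chrom"),
               vapply(ginfo, `[[`, numeric(1), "start"))
  ginfo <- ginfo[ord]

  pairs <- list()
  for (sym in names(models)) {
    m <- models[[sym]]
    span_bases <- seq_bases(m$span[1], m$span[2])
    for (gi in seq_along(ginfo)) {
      g <- ginfo[[gi]]
      if (!any(g$members %in% cand[[sym]])) next
      ex_w <- length(intersect(g$bases, m$exon_bases))
      sp_w <- length(intersect(g$bases, span_bases))
      pr_w <- length(intersect(g$bases, m$prom_bases))
      flags <- character(0)
      if (ex_w >= min_overlap) flags <- c(flags, "exonic")
      else if (sp_w >= min_overlap) flags <- c(flags, "intronic")
      if (pr_w >= min_overlap) flags <- c(flags, "promoter")
      if (length(flags) == 0L) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_symbol = sym, members = paste(g$members, collapse = ","),
        label = paste(flags, collapse = "; "), stringsAsFactors = FALSE)
    }
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(gene_symbol = character(), members = character(),
                    label = character()),
       partition = lapply(ginfo, `[[`, "members"))
}

# connected components of the exonic-overlap graph over given transcripts
oracle_components <- function(ann, tids) {
  n <- length(tids)
  if (n == 0L) return(integer(0))
  bases <- lapply(tids, function(t)
    iv_bases(ann$exons[ann$exons$transcript_id == t, ]))
  meta <- ann$transcripts[match(tids, ann$transcripts$transcript_id), ]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- meta$chrom[i] == meta$chrom[j] &&
      meta$strand[i] == meta$strand[j] &&
      length(intersect(bases[[i]], bases[[j]])) >= 1L
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    return(igraph::components(g)$membership)
  }
  # naive transitive closure fallback
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# pair summary of a nat_report, comparable with oracle_discover output
report_pair_keys <- function(report) {
  if (nrow(report$pairs) == 0L) return(character(0))
  sort(paste(report$pairs$gene_symbol, report$pairs$transcripts,
             report$pairs$label, sep = " | "))
}

oracle_pair_keys <- function(orc) {
  if (nrow(orc$pairs) == 0L) return(character(0))
  sort(paste(orc$pairs$gene_symbol, orc$pairs$members, orc$pairs$label,
             sep = " | "))
}

# per-base mask oracle for non-junction assay regions
oracle_assay_masks <- function(model, locus, min_length) {
  ab <- iv_bases(locus$exon_union)
  sense_ex <- iv_bases(model$exon_union)
  span_b <- seq_bases(model$span[1], model$span[2])
  prom_b <- seq_bases(model$promoter[1], model$promoter[2])
  free <- setdiff(ab, sense_ex)
  cat_of <- ifelse(free %in% span_b, "SENSE_INTRON_OVERLAP",
            ifelse(free %in% prom_b, "PROMOTER_OVERLAP", "NONOVERLAP_EXON"))
  if (length(free) == 0L)
    return(data.frame(kind = character(), start = numeric(),
                      end = numeric()))
  o <- order(free); free <- free[o]; cat_of <- cat_of[o]
  run_id <- cumsum(c(TRUE, diff(free) != 1L | cat_of[-1] != cat_of[-length(cat_of)]))
  out <- do.call(rbind, lapply(split(seq_along(free), run_id), function(idx)
    data.frame(kind = cat_of[idx[1]], start = as.numeric(free[idx[1]]),
               end = as.numeric(free[idx[length(idx)]] + 1))))
  out <- out[out$end - out$start >= min_length, , drop = FALSE]
  out[order(match(out$kind, c("SPLICE_JUNCTION", "NONOVERLAP_EXON",
                              "SENSE_INTRON_OVERLAP", "PROMOTER_OVERLAP")),
            out$start), , drop = FALSE]
}

# small GTF builder for hand-made fixtures
gtf_line <- function(chrom, feature, start0, end0, strand, gene, tx,
                     biotype = NULL, frame = ".") {
  bt <- if (is.null(biotype)) "" else sprintf(' transcript_biotype "%s";',
                                              biotype)
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\tgene_id "%s"; transcript_id "%s";%s',
          chrom, feature, start0 + 1L, end0, strand, frame, gene, tx, bt)
}
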