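#' Find opposite-strand candidate transcripts for a gene model
#'
#' Returns every transcript on the same chromosome and opposite strand whose
#' span intersects the union of the gene's span and promoter window.
#' Transcripts of the query gene itself are excluded.
#'
#' @param model A `gene_model`.
#' @param annotation A `nat_annotation`.
#' @return Character vector of transcript ids (possibly empty).
#' @export
find_antisense_candidates <- function(model, annotation) {
  tx <- annotation$transcripts
  lo <- min(model$span[1], model$promoter[1])
  hi <- max(model$span[2], model$promoter[2])
  opp <- if (model$strand == "+") "-" else "+"
  hit <- tx$chrom == model$chrom & tx$strand == opp &
    tx$start < hi & tx$end > lo &
    tolower(tx$gene_id) != tolower(model$gene_id)
  tx$transcript_id[hit]
}

#' Noncoding filter
#'
#' Applies the coding-status policy: `coding` transcripts are never
#' noncoding; `noncoding` always are; `unknown` passes only under the
#' permissive policy.
#'
#' @param coding_flag Character vector of flags (`coding`, `noncoding`,
#'   `unknown`), or a `nat_annotation` row subset's `coding_flag`.
#' @param policy `"strict"` or `"permissive"`.
#' @return Logical vector.
#' @export
is_noncoding <- function(coding_flag, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  ifelse(coding_flag == "coding", FALSE,
         ifelse(coding_flag == "noncoding", TRUE, policy == "permissive"))
}

#' Group antisense transcripts into loci by exonic overlap
#'
#' Single-linkage clustering: two same-strand transcripts belong to the same
#' locus when their exons overlap by at least 1 bp, directly or through a
#' chain of such overlaps. Locus ids are deterministic, ordered by
#' (chromosome, span start).
#'
#' @param annotation A `nat_annotation`.
#' @param transcript_ids Transcripts to group (must exist in the annotation).
#' @return A list of `antisense_locus` objects, each with `locus_id`,
#'   `chrom`, `strand`, `transcript_ids`, `exon_union`, `span` and
#'   `member_exons` (per-transcript exon table).
#' @export
group_into_loci <- function(annotation, transcript_ids) {
  if (length(transcript_ids) == 0L) return(list())
  tx <- annotation$transcripts
  tx <- tx[match(unique(transcript_ids), tx$transcript_id), , drop = FALSE]
  if (anyNA(tx$transcript_id)) stop("unknown transcript id in grouping input")
  ex <- annotation$exons[annotation$exons$transcript_id %in%
                           tx$transcript_id, , drop = FALSE]
  # union-find over transcripts, edges from exon-exon overlap per chrom/strand
  ids <- tx$transcript_id
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (key in unique(paste(ex$chrom, ex$strand))) {
    sel <- paste(ex$chrom, ex$strand) == key
    e <- ex[sel, , drop = FALSE]
    ir <- iv_to_ir(iv_df(e$start, e$end))
    hits <- IRanges::findOverlaps(ir, ir, minoverlap = 1L)
    qi <- match(e$transcript_id[S4Vectors::queryHits(hits)], ids)
    si <- match(e$transcript_id[S4Vectors::subjectHits(hits)], ids)
    for (k in seq_along(qi)) if (qi[k] != si[k]) unite(qi[k], si[k])
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  groups <- split(ids, comp)
  loci <- lapply(groups, function(members) {
    e <- ex[ex$transcript_id %in% members, , drop = FALSE]
    exu <- iv_merge(iv_df(e$start, e$end))
    structure(list(locus_id = NA_character_, chrom = e$chrom[1],
                   strand = e$strand[1], transcript_ids = sort(members),
                   exon_union = exu,
                   span = c(min(exu$start), max(exu$end)),
                   member_exons = e[order(e$transcript_id, e$start), ,
                                    drop = FALSE]),
              class = "antisense_locus")
  })
  ord <- order(vapply(loci, `[[`, character(1), "chrom"),
               vapply(loci, function(l) l$span[1], numeric(1)),
               vapply(loci, function(l) l$span[2], numeric(1)))
  loci <- loci[ord]
  for (i in seq_along(loci))
    loci[[i]]$locus_id <- sprintf("NATL%04d", i)
  loci
}

#' @export
print.antisense_locus <- function(x, ...) {
  cat(sprintf("antisense_locus %s  %s:%d-%d (%s)  %d transcripts\n",
              x$locus_id, x$chrom, x$span[1], x$span[2], x$strand,
              length(x$transcript_ids)))
  invisible(x)
}

OVERLAP_FLAGS <- c("exonic", "intronic", "promoter")
LEGAL_LABELS <- c("exonic", "intronic", "promoter",
                  "exonic; promoter", "intronic; promoter")

#' Classify a sense-antisense overlap
#'
#' Flags, per the overlap taxonomy:
#' * `exonic` — an antisense exon intersects the sense merged exon cover;
#' * `intronic` — no exonic intersection, but the antisense exons intersect
#'   the sense gene body (i.e. lie over intronic sequence); mutually
#'   exclusive with `exonic`;
#' * `promoter` — an antisense exon intersects the sense promoter window;
#'   additive with either of the other two.
#'
#' All intersections are tested against antisense *exons* (not the locus
#' span), each requiring at least `min_overlap` bp.
#'
#' @param model A `gene_model` (sense side).
#' @param locus An `antisense_locus` (opposite strand, same chromosome).
#' @param min_overlap Minimum overlap in bp to call a flag.
#' @return A list of class `overlap_classification` with `flags` (character
#'   subset of exonic/intronic/promoter) and `label` (flags joined by "; ").
#'   Empty flags mean no reportable overlap.
#' @export
classify_overlap <- function(model, locus, min_overlap = 1) {
  if (identical(model$strand, locus$strand))
    stop("classify_overlap requires opposite strands (got both '",
         model$strand, "')")
  if (!identical(model$chrom, locus$chrom))
    stop("classify_overlap requires the same chromosome")
  aex <- locus$exon_union
  exonic_w <- iv_intersect_width(aex, model$exon_union)
  span_w <- iv_intersect_width(aex, iv_df(model$span[1], model$span[2]))
  prom_w <- if (model$promoter[2] > model$promoter[1])
    iv_intersect_width(aex, iv_df(model$promoter[1], model$promoter[2]))
  else 0
  flags <- character(0)
  if (exonic_w >= min_overlap) flags <- c(flags, "exonic")
  else if (span_w >= min_overlap) flags <- c(flags, "intronic")
  if (prom_w >= min_overlap) flags <- c(flags, "promoter")
  structure(list(flags = flags,
                 label = paste(flags, collapse = "; ")),
            class = "overlap_classification")
}

#' Discover natural antisense transcripts for a gene list
#'
#' Composes the full pipeline: build gene models from the annotation, scan
#' each model for opposite-strand transcripts over its span or promoter,
#' drop coding transcripts, group the survivors into antisense loci by
#' exonic overlap, classify each sense-locus overlap and emit one pair per
#' (gene, locus) with a non-empty flag set. A locus paired with several
#' genes is counted once in `n_nat_loci` but contributes one pair (and one
#' histogram entry) per gene.
#'
#' @param annotation A `nat_annotation`.
#' @param gene_list Character vector of gene symbols to query.
#' @param config A [nat_config()].
#' @param aliases Optional alias map passed to [build_gene_models()].
#' @return An object of class `nat_report`: `pairs` (data.frame), `loci`
#'   (list of `antisense_locus`), counts (`n_genes_queried`,
#'   `n_genes_with_nat`, `n_nat_loci`, `mean_loci_per_positive_gene`),
#'   `class_histogram`, `unmatched`, `ambiguous`, `excluded_unknown`
#'   (transcripts dropped for unknown coding status under the strict
#'   policy), and `models`.
#' @export
discover_nats <- function(annotation, gene_list, config = nat_config(),
                          aliases = NULL) {
  if (length(gene_list) == 0L)
    return(new_nat_report(empty_pairs_table(), list(), 0L, list(), gm = NULL,
                          excluded = character(0)))
  gm <- build_gene_models(annotation, gene_list,
                          promoter_window = config$promoter_window,
                          aliases = aliases)
  tx <- annotation$transcripts
  cand_by_gene <- lapply(gm$models, find_antisense_candidates, annotation)
  all_cand <- unique(unlist(cand_by_gene, use.names = FALSE))
  flags <- tx$coding_flag[match(all_cand, tx$transcript_id)]
  keep <- is_noncoding(flags, config$coding_policy)
  excluded_unknown <- all_cand[flags == "unknown" & !keep]
  nc <- all_cand[keep]
  loci <- group_into_loci(annotation, nc)
  tx2locus <- stats::setNames(
    rep(vapply(loci, `[[`, character(1), "locus_id"),
        vapply(loci, function(l) length(l$transcript_ids), integer(1))),
    unlist(lapply(loci, `[[`, "transcript_ids")))
  names(loci) <- vapply(loci, `[[`, character(1), "locus_id")

  rows <- list()
  for (sym in names(gm$models)) {
    model <- gm$models[[sym]]
    lids <- unique(tx2locus[intersect(cand_by_gene[[sym]], names(tx2locus))])
    if (length(lids) == 0L) next
    lids <- lids[order(vapply(loci[lids], function(l) l$span[1], numeric(1)))]
    for (lid in lids) {
      locus <- loci[[lid]]
      cls <- classify_overlap(model, locus, min_overlap = config$min_overlap)
      if (length(cls$flags) == 0L) next
      span_iv <- genome_interval(locus$chrom, locus$span[1], locus$span[2],
                                 locus$strand)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = sym, locus_id = lid,
        transcripts = paste(locus$transcript_ids, collapse = ","),
        chrom = locus$chrom, start = locus$span[1], end = locus$span[2],
        strand = locus$strand, coords = format_span_string(span_iv),
        exonic = "exonic" %in% cls$flags,
        intronic = "intronic" %in% cls$flags,
        promoter = "promoter" %in% cls$flags,
        label = cls$label, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty_pairs_table()
  rownames(pairs) <- NULL
  used <- unique(pairs$locus_id)
  new_nat_report(pairs, loci[names(loci) %in% used],
                 length(gene_list), gm$models, gm = gm,
                 excluded = excluded_unknown)
}

empty_pairs_table <- function() data.frame(
  gene_symbol = character(), locus_id = character(), transcripts = character(),
  chrom = character(), start = numeric(), end = numeric(),
  strand = character(), coords = character(), exonic = logical(),
  intronic = logical(), promoter = logical(), label = character(),
  stringsAsFactors = FALSE)

new_nat_report <- function(pairs, loci, n_queried, models, gm, excluded) {
  n_pos <- length(unique(pairs$gene_symbol))
  n_loci <- length(unique(pairs$locus_id))
  structure(list(
    pairs = pairs, loci = loci,
    n_genes_queried = as.integer(n_queried),
    n_genes_with_nat = as.integer(n_pos),
    n_nat_loci = as.integer(n_loci),
    mean_loci_per_positive_gene = if (n_pos > 0) n_loci / n_pos else NA_real_,
    class_histogram = class_histogram(pairs),
    unmatched = if (is.null(gm)) character(0) else gm$unmatched,
    ambiguous = if (is.null(gm)) character(0) else gm$ambiguous,
    excluded_unknown = excluded,
    models = models), class = "nat_report")
}

#' Histogram of overlap classes over report pairs
#'
#' Counts pairs per legal flag combination (exonic, intronic, promoter,
#' exonic; promoter, intronic; promoter). Counted per pair: a locus paired
#' with several genes contributes once per pairing.
#'
#' @param pairs A `nat_report` or its `pairs` data.frame.
#' @return Named integer vector over the five legal labels.
#' @export
class_histogram <- function(pairs) {
  if (inherits(pairs, "nat_report")) pairs <- pairs$pairs
  out <- stats::setNames(integer(length(LEGAL_LABELS)), LEGAL_LABELS)
  if (nrow(pairs) > 0L) {
    tab <- table(factor(pairs$label, levels = LEGAL_LABELS))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' @export
print.nat_report <- function(x, ...) {
  cat(sprintf("nat_report: %d/%d queried genes have >=1 antisense locus; %d loci, %d pairs\n",
              x$n_genes_with_nat, x$n_genes_queried, x$n_nat_loci,
              nrow(x$pairs)))
  if (x$n_genes_with_nat > 0)
    cat(sprintf("  mean loci per positive gene: %.2f\n",
                x$mean_loci_per_positive_gene))
  h <- x$class_histogram
  cat("  overlap classes:",
      paste(names(h)[h > 0], h[h > 0], sep = "=", collapse = ", "), "\n")
  if (length(x$unmatched))
    cat("  unmatched symbols:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}

#' Write report outputs (pairs TSV, report JSON, loci BED6)
#'
#' @param report A `nat_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs_path <- file.path(dir, "pairs.tsv")
  utils::write.table(report$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    n_genes_queried = report$n_genes_queried,
    n_genes_with_nat = report$n_genes_with_nat,
    n_nat_loci = report$n_nat_loci,
    mean_loci_per_positive_gene = report$mean_loci_per_positive_gene,
    class_histogram = as.list(report$class_histogram),
    unmatched = report$unmatched,
    ambiguous = report$ambiguous), json_path, auto_unbox = TRUE, digits = NA)
  bed_path <- file.path(dir, "loci.bed")
  if (length(report$loci)) {
    bed <- data.frame(
      chrom = vapply(report$loci, `[[`, character(1), "chrom"),
      start = vapply(report$loci, function(l) l$span[1], numeric(1)),
      end = vapply(report$loci, function(l) l$span[2], numeric(1)),
      name = vapply(report$loci, `[[`, character(1), "locus_id"),
      strand = vapply(report$loci, `[[`, character(1), "strand"))
  } else {
    bed <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), strand = character())
  }
  write_bed6(bed, bed_path)
  invisible(c(pairs = pairs_path, report = json_path, loci = bed_path))
}
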