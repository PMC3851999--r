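#' Build gene models for a list of gene symbols
#'
#' A gene model is the union of all alternative isoforms of one gene: the
#' merged exon cover, the genomic span, and a strand-aware promoter window
#' immediately upstream of the 5'-most transcription start (upstream of the
#' minimum start on `+`, downstream of the maximum end on `-`).
#'
#' Symbol matching is case-insensitive against `gene_id`, optionally through
#' an alias map. Symbols that match nothing are reported in `unmatched`;
#' genes whose transcripts mix chromosomes or strands are excluded and
#' reported in `ambiguous` — neither is ever silently dropped.
#'
#' @param annotation A `nat_annotation` from [read_gtf()].
#' @param gene_list Character vector of gene symbols.
#' @param promoter_window Promoter window length in bp (default 1000).
#' @param aliases Optional named character vector mapping alias -> symbol
#'   as used in the annotation.
#' @return A list with `models` (named list of `gene_model` objects, in
#'   gene-list order), `unmatched` (character) and `ambiguous` (character).
#' @export
build_gene_models <- function(annotation, gene_list, promoter_window = 1000,
                              aliases = NULL) {
  stopifnot(length(gene_list) > 0L, promoter_window >= 0)
  tx <- annotation$transcripts
  models <- list(); unmatched <- character(0); ambiguous <- character(0)
  for (sym in gene_list) {
    query <- sym
    if (!is.null(aliases) && tolower(sym) %in% tolower(names(aliases)))
      query <- aliases[[which(tolower(names(aliases)) == tolower(sym))[1]]]
    hit <- tx[tolower(tx$gene_id) == tolower(query), , drop = FALSE]
    if (nrow(hit) == 0L) { unmatched <- c(unmatched, sym); next }
    if (length(unique(hit$chrom)) > 1L || length(unique(hit$strand)) > 1L) {
      ambiguous <- c(ambiguous, sym); next
    }
    ex <- annotation$exons[annotation$exons$transcript_id %in%
                             hit$transcript_id, , drop = FALSE]
    exon_union <- iv_merge(iv_df(ex$start, ex$end))
    span <- c(min(exon_union$start), max(exon_union$end))
    strand <- hit$strand[1]
    promoter <- if (strand == "-")
      c(span[2], span[2] + promoter_window)
    else
      c(max(0, span[1] - promoter_window), span[1])
    models[[sym]] <- structure(list(
      gene_symbol = sym, gene_id = hit$gene_id[1], chrom = hit$chrom[1],
      strand = strand, transcript_ids = hit$transcript_id,
      exon_union = exon_union, span = span, promoter = promoter,
      promoter_window = promoter_window), class = "gene_model")
  }
  list(models = models, unmatched = unmatched, ambiguous = ambiguous)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d isoforms, %d merged exons\n",
              x$gene_symbol, x$chrom, x$span[1], x$span[2], x$strand,
              length(x$transcript_ids), nrow(x$exon_union)))
  invisible(x)
}

#' Write an unmatched/ambiguous gene report as TSV
#'
#' @param gm Result of [build_gene_models()].
#' @param file Output path.
#' @export
write_gene_report <- function(gm, file) {
  out <- rbind(
    if (length(gm$unmatched)) data.frame(symbol = gm$unmatched,
                                         status = "unmatched"),
    if (length(gm$ambiguous)) data.frame(symbol = gm$ambiguous,
                                         status = "ambiguous"))
  if (is.null(out)) out <- data.frame(symbol = character(),
                                      status = character())
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
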