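ASSAY_KINDS <- c("SPLICE_JUNCTION", "NONOVERLAP_EXON",
                 "SENSE_INTRON_OVERLAP", "PROMOTER_OVERLAP")

#' Enumerate qPCR-measurable regions of an antisense locus
#'
#' Follows the primer-placement rules used for strand-safe antisense
#' quantification: a splice junction is preferred when the antisense
#' transcript is spliced; otherwise an exonic stretch that either does not
#' overlap the sense gene at all, or overlaps only an intron or the promoter
#' of the sense gene, in which case strand-specific reverse transcription is
#' required to avoid amplifying the sense pre-mRNA.
#'
#' Emitted kinds:
#' * `SPLICE_JUNCTION` — one per distinct exon-exon junction across the
#'   locus members; the region is the terminal stretch (up to `min_length`
#'   bp) of the upstream flanking exon, with both flanking exons recorded in
#'   the `junction_*` columns. Junction-spanning assays need neither
#'   strand-specific RT nor a no-RT control.
#' * `NONOVERLAP_EXON` — antisense exon sequence outside the sense span and
#'   promoter.
#' * `SENSE_INTRON_OVERLAP` / `PROMOTER_OVERLAP` — antisense exon sequence
#'   over a sense intron / the sense promoter; both require strand-specific
#'   RT.
#'
#' Non-junction candidates are computed as the antisense exon union minus
#' the sense exon union, split at the sense span and promoter boundaries
#' into maximal homogeneous pieces; each piece must be at least `min_length`
#' bp. All non-junction regions require a no-RT control (they lie in a
#' single exon, so genomic DNA would amplify too).
#'
#' @param model Sense `gene_model`.
#' @param locus Antisense `antisense_locus`.
#' @param min_length Minimum region length in bp (default 60).
#' @return data.frame with columns kind, chrom, start, end, strand, width,
#'   strand_specific_required, no_rt_control_required, junction_left_start,
#'   junction_left_end, junction_right_start, junction_right_end. Zero rows
#'   (with a `diagnostic` attribute `"no safe region"`) when nothing
#'   qualifies.
#' @export
enumerate_assay_regions <- function(model, locus, min_length = 60) {
  stopifnot(min_length > 0)
  rows <- list()
  add <- function(kind, start, end, jl = c(NA, NA), jr = c(NA, NA)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, chrom = locus$chrom, start = start, end = end,
      strand = locus$strand, width = end - start,
      strand_specific_required = kind %in% c("SENSE_INTRON_OVERLAP",
                                             "PROMOTER_OVERLAP"),
      no_rt_control_required = kind != "SPLICE_JUNCTION",
      junction_left_start = jl[1], junction_left_end = jl[2],
      junction_right_start = jr[1], junction_right_end = jr[2],
      stringsAsFactors = FALSE)
  }
  # splice junctions, deduplicated across member isoforms
  seen <- character(0)
  me <- locus$member_exons
  for (tid in unique(me$transcript_id)) {
    e <- me[me$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    for (j in seq_len(nrow(e) - 1L)) {
      key <- paste(e$end[j], e$start[j + 1L])
      if (key %in% seen) next
      seen <- c(seen, key)
      anchor_start <- max(e$start[j], e$end[j] - min_length)
      add("SPLICE_JUNCTION", anchor_start, e$end[j],
          jl = c(e$start[j], e$end[j]),
          jr = c(e$start[j + 1L], e$end[j + 1L]))
    }
  }
  # exonic stretches clear of the sense exon union, split by sense masks
  free <- iv_subtract(locus$exon_union, model$exon_union)
  span_iv <- iv_df(model$span[1], model$span[2])
  prom_iv <- if (model$promoter[2] > model$promoter[1])
    iv_df(model$promoter[1], model$promoter[2]) else iv_df(numeric(0), numeric(0))
  pieces <- list(SENSE_INTRON_OVERLAP = iv_intersect(free, span_iv),
                 PROMOTER_OVERLAP = iv_intersect(free, prom_iv),
                 NONOVERLAP_EXON = iv_subtract(iv_subtract(free, span_iv),
                                               prom_iv))
  for (kind in names(pieces)) {
    p <- pieces[[kind]]
    p <- p[p$end - p$start >= min_length, , drop = FALSE]
    for (i in seq_len(nrow(p))) add(kind, p$start[i], p$end[i])
  }
  if (length(rows) == 0L) {
    out <- empty_assay_table()
    attr(out, "diagnostic") <- "no safe region"
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$kind, ASSAY_KINDS), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_assay_table <- function() data.frame(
  kind = character(), chrom = character(), start = numeric(), end = numeric(),
  strand = character(), width = numeric(), strand_specific_required = logical(),
  no_rt_control_required = logical(), junction_left_start = numeric(),
  junction_left_end = numeric(), junction_right_start = numeric(),
  junction_right_end = numeric(), stringsAsFactors = FALSE)

#' Select the best assay region
#'
#' Priority: splice junction, then exon sequence outside the sense gene,
#' then sense-intron overlap, then promoter overlap; ties broken by longer
#' region, then left-most start, then left-most end. The ordering is total,
#' so the choice is invariant to the input order.
#'
#' @param regions data.frame from [enumerate_assay_regions()].
#' @return The selected row (one-row data.frame).
#' @export
select_assay_region <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L)
    stop("no measurable region available for this locus")
  ord <- order(match(regions$kind, ASSAY_KINDS), -regions$width,
               regions$start, regions$end)
  regions[ord[1], , drop = FALSE]
}

#' Write assay regions as TSV and BED6
#'
#' @param regions data.frame from [enumerate_assay_regions()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and `<prefix>.bed`.
#' @export
write_assay_regions <- function(regions, prefix) {
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(regions, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- paste0(prefix, ".bed")
  if (nrow(regions)) {
    write_bed6(data.frame(chrom = regions$chrom, start = regions$start,
                          end = regions$end, name = regions$kind,
                          strand = regions$strand), bed)
  } else write_bed6(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), name = character(),
                               strand = character()), bed)
  invisible(c(tsv = tsv, bed = bed))
}
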