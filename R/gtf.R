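#' Read a GTF transcript annotation
#'
#' Parses 9-column GTF into a `nat_annotation`: a transcript table (one row
#' per transcript, with span and coding status) plus an exon table. Input
#' coordinates are 1-based inclusive and are converted to the internal
#' 0-based half-open convention.
#'
#' Coding status is resolved by precedence: any CDS row for the transcript
#' makes it `coding`; otherwise a biotype-like attribute is consulted
#' (dialect `ensembl`: `transcript_biotype`, `gene_biotype`,
#' `transcript_type`, `gene_type`; dialect `aceview`: `transcript_type`,
#' `type`); otherwise the flag is `unknown`.
#'
#' Malformed lines (wrong column count, inverted coordinates, transcripts
#' whose exons mix chromosomes or strands) are never fatal: they are recorded
#' with line numbers in the `errors` element and the offending records are
#' dropped.
#'
#' @param file Path to a GTF file, or `NULL` when `text` is given.
#' @param dialect Attribute dialect, `"ensembl"` or `"aceview"`.
#' @param text Optional character vector of GTF lines (instead of `file`).
#' @return An object of class `nat_annotation` with elements `transcripts`
#'   (data.frame: transcript_id, gene_id, chrom, strand, start, end,
#'   n_exons, coding_flag), `exons` (data.frame: transcript_id, chrom,
#'   strand, start, end; sorted, merged per transcript), `attrs` (named list
#'   of attribute vectors per transcript), `dialect`, and `errors`
#'   (data.frame: line, message).
#' @export
read_gtf <- function(file = NULL, dialect = c("ensembl", "aceview"),
                     text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (!file.exists(file)) stop("GTF file not found: ", file)
    text <- readLines(file, warn = FALSE)
  }
  n <- length(text)
  errors <- list()
  keep <- !grepl("^\\s*(#|$)", text)
  lineno <- which(keep)
  fields <- strsplit(text[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf != 9L
  for (i in which(bad))
    errors[[length(errors) + 1L]] <-
      data.frame(line = lineno[i],
                 message = sprintf("expected 9 tab-separated columns, got %d", nf[i]))
  fields <- fields[!bad]; lineno <- lineno[!bad]
  if (length(fields) == 0L) {
    return(new_annotation(empty_tx_table(), empty_exon_table(), list(),
                          dialect, bind_errors(errors)))
  }
  mat <- do.call(rbind, fields)
  feature <- mat[, 3L]
  sel <- feature %in% c("exon", "CDS")
  mat <- mat[sel, , drop = FALSE]; lineno <- lineno[sel]
  start1 <- suppressWarnings(as.numeric(mat[, 4L]))
  end1 <- suppressWarnings(as.numeric(mat[, 5L]))
  bad <- !is.finite(start1) | !is.finite(end1) | start1 > end1
  for (i in which(bad))
    errors[[length(errors) + 1L]] <-
      data.frame(line = lineno[i],
                 message = sprintf("invalid coordinates %s-%s", mat[i, 4L], mat[i, 5L]))
  mat <- mat[!bad, , drop = FALSE]
  start0 <- start1[!bad] - 1; end0 <- end1[!bad]
  lineno <- lineno[!bad]
  attrs <- lapply(mat[, 9L], parse_gtf_attrs)
  tid <- vapply(attrs, function(a) a[["transcript_id"]] %||% NA_character_,
                character(1))
  gid <- vapply(attrs, function(a) a[["gene_id"]] %||% NA_character_,
                character(1))
  noid <- is.na(tid)
  for (i in which(noid))
    errors[[length(errors) + 1L]] <-
      data.frame(line = lineno[i], message = "missing transcript_id attribute")
  rows <- data.frame(transcript_id = tid, gene_id = gid,
                     chrom = mat[, 1L], feature = mat[, 3L],
                     strand = mat[, 7L], start = start0, end = end0,
                     line = lineno, stringsAsFactors = FALSE)[!noid, , drop = FALSE]
  attrs <- attrs[!noid]

  tx_ids <- unique(rows$transcript_id)
  exl <- split(rows, factor(rows$transcript_id, levels = tx_ids))
  tx_list <- vector("list", length(tx_ids))
  ex_list <- vector("list", length(tx_ids))
  attr_list <- vector("list", length(tx_ids))
  names(attr_list) <- tx_ids
  ok <- logical(length(tx_ids))
  first_idx <- match(tx_ids, rows$transcript_id)
  for (k in seq_along(tx_ids)) {
    r <- exl[[k]]
    if (length(unique(r$chrom)) > 1L || length(unique(r$strand)) > 1L) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = r$line[1],
                   message = sprintf("transcript %s mixes chromosomes or strands",
                                     tx_ids[k]))
      next
    }
    ex <- r[r$feature == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- r   # CDS-only records still define extent
    exu <- iv_merge(iv_df(ex$start, ex$end))
    has_cds <- any(r$feature == "CDS")
    flag <- if (has_cds) "coding"
            else biotype_flag(attrs[[first_idx[k]]], dialect)
    tx_list[[k]] <- data.frame(
      transcript_id = tx_ids[k], gene_id = r$gene_id[1], chrom = r$chrom[1],
      strand = r$strand[1], start = min(exu$start), end = max(exu$end),
      n_exons = nrow(exu), coding_flag = flag, stringsAsFactors = FALSE)
    ex_list[[k]] <- data.frame(
      transcript_id = tx_ids[k], chrom = r$chrom[1], strand = r$strand[1],
      start = exu$start, end = exu$end, stringsAsFactors = FALSE)
    attr_list[[k]] <- attrs[[first_idx[k]]]
    ok[k] <- TRUE
  }
  tx <- if (any(ok)) do.call(rbind, tx_list[ok]) else empty_tx_table()
  ex <- if (any(ok)) do.call(rbind, ex_list[ok]) else empty_exon_table()
  rownames(tx) <- NULL; rownames(ex) <- NULL
  new_annotation(tx, ex, attr_list[ok], dialect, bind_errors(errors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_gtf_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
  keys <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_,
                 character(1))
  vals <- vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_,
                 character(1))
  keep <- !is.na(keys)
  stats::setNames(as.list(vals[keep]), keys[keep])
}

NONCODING_PAT <- "non[_-]?coding|noncoding|ncRNA|lncRNA|lincRNA|antisense|pseudogene"
CODING_PAT <- "protein_coding|mRNA|^coding$"

biotype_flag <- function(attrs, dialect) {
  keys <- switch(dialect,
    ensembl = c("transcript_biotype", "gene_biotype", "transcript_type",
                "gene_type"),
    aceview = c("transcript_type", "type"))
  for (k in keys) {
    v <- attrs[[k]]
    if (is.null(v)) next
    if (grepl(NONCODING_PAT, v, ignore.case = TRUE)) return("noncoding")
    if (grepl(CODING_PAT, v, ignore.case = TRUE)) return("coding")
  }
  "unknown"
}

empty_tx_table <- function() data.frame(
  transcript_id = character(), gene_id = character(), chrom = character(),
  strand = character(), start = numeric(), end = numeric(),
  n_exons = integer(), coding_flag = character(), stringsAsFactors = FALSE)

empty_exon_table <- function() data.frame(
  transcript_id = character(), chrom = character(), strand = character(),
  start = numeric(), end = numeric(), stringsAsFactors = FALSE)

bind_errors <- function(errors) {
  if (length(errors) == 0L)
    return(data.frame(line = integer(), message = character()))
  do.call(rbind, errors)
}

new_annotation <- function(tx, ex, attrs, dialect, errors) {
  structure(list(transcripts = tx, exons = ex, attrs = attrs,
                 dialect = dialect, errors = errors),
            class = "nat_annotation")
}

#' @export
print.nat_annotation <- function(x, ...) {
  cat(sprintf("nat_annotation: %d transcripts, %d genes (%s dialect)\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              x$dialect))
  tab <- table(x$transcripts$coding_flag)
  cat("  coding status:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  if (nrow(x$errors) > 0L)
    cat(sprintf("  %d malformed records skipped (see $errors)\n",
                nrow(x$errors)))
  invisible(x)
}

#' Write an annotation back to GTF
#'
#' Emits exon rows for every transcript (converting to 1-based inclusive
#' coordinates), CDS rows for coding transcripts and a
#' `transcript_biotype "noncoding"` attribute for noncoding ones, so that
#' re-reading reproduces the transcript set including coding flags.
#'
#' @param annotation A `nat_annotation`.
#' @param file Output path.
#' @export
write_gtf <- function(annotation, file) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    e <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    bt <- switch(tx$coding_flag[i],
                 coding = ' transcript_biotype "protein_coding";',
                 noncoding = ' transcript_biotype "noncoding";',
                 "")
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                        tx$gene_id[i], tx$transcript_id[i], bt)
    lines <- c(lines, sprintf("%s\tnatkit\texon\t%d\t%d\t.\t%s\t.\t%s",
                              e$chrom, as.integer(e$start) + 1L,
                              as.integer(e$end), e$strand, attr_str))
    if (tx$coding_flag[i] == "coding")
      lines <- c(lines, sprintf("%s\tnatkit\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                e$chrom, as.integer(e$start) + 1L,
                                as.integer(e$end), e$strand, attr_str))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a gene list (one symbol per line, '#' comments allowed)
#'
#' @param file Path to the gene list.
#' @return Character vector of symbols, in file order, duplicates removed.
#' @export
read_gene_list <- function(file) {
  if (!file.exists(file)) stop("gene list file not found: ", file)
  x <- readLines(file, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Write intervals as BED6
#'
#' @param df data.frame with columns chrom, start, end, name, strand and
#'   optionally score.
#' @param file Output path.
#' @export
write_bed6 <- function(df, file) {
  score <- if ("score" %in% names(df)) df$score else 0
  out <- data.frame(df$chrom, as.integer(df$start), as.integer(df$end),
                    df$name, score, df$strand)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
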