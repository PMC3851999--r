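KNOWN_CLASS_CODES <- c("=", "c", "j", "e", "i", "o", "p", "r", "u", "x", "s",
                       ".")

#' Read a fragment quantification table
#'
#' A tracking-style TSV with header columns `fragment_id`, `locus_id`,
#' `class_code`, `fpkm` and either a `compartment` column (long format) or a
#' `compartment` argument naming the compartment of the whole file.
#'
#' @param file Path to the TSV.
#' @param compartment Optional compartment label applied to every row.
#' @return data.frame of fragment records.
#' @export
read_fragment_table <- function(file, compartment = NULL) {
  if (!file.exists(file)) stop("fragment table not found: ", file)
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("fragment_id", "locus_id", "class_code", "fpkm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fragment table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(compartment)) df$compartment <- compartment
  if (!"compartment" %in% names(df))
    stop("fragment table has no compartment column and none was supplied")
  if (any(!is.finite(df$fpkm) | df$fpkm < 0))
    stop("fragment table contains negative or non-finite FPKM values")
  df
}

#' Filter out fragments from excluded structural classes
#'
#' Removes fragments whose class code marks them as intronic or incompletely
#' spliced (default codes `i` and `e`), keeping input order. Codes outside
#' the known vocabulary are kept with a warning, never silently dropped.
#'
#' @param records Fragment data.frame (see [read_fragment_table()]).
#' @param excluded_codes Class codes to remove.
#' @param known_codes Vocabulary used for the unknown-code warning.
#' @return The surviving records; attribute `n_removed` carries the count.
#' @export
filter_fragments <- function(records, excluded_codes = c("i", "e"),
                             known_codes = KNOWN_CLASS_CODES) {
  unknown <- setdiff(unique(records$class_code),
                     union(known_codes, excluded_codes))
  if (length(unknown))
    warning("unknown class code(s) kept: ", paste(unknown, collapse = ", "))
  drop <- records$class_code %in% excluded_codes
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Aggregate fragment FPKM into locus expression per compartment
#'
#' Locus expression is the sum of FPKM over surviving fragments assigned to
#' the locus, per subcellular compartment. Loci with no surviving fragment
#' in a compartment get 0 there.
#'
#' @param records Filtered fragment data.frame.
#' @param compartments Compartment set (columns of the output); defaults to
#'   the compartments present, in the standard cytoplasm/nucleoplasm/
#'   chromatin order when applicable.
#' @return data.frame of class `locus_expression`: `locus_id` plus one FPKM
#'   column per compartment.
#' @export
aggregate_locus_fpkm <- function(records,
                                 compartments = c("cytoplasm", "nucleoplasm",
                                                  "chromatin")) {
  if (any(records$fpkm < 0)) stop("negative FPKM in fragment records")
  extra <- setdiff(unique(records$compartment), compartments)
  compartments <- c(compartments[compartments %in%
                                   union(records$compartment, compartments)],
                    extra)
  loci <- unique(records$locus_id)
  out <- data.frame(locus_id = loci, stringsAsFactors = FALSE)
  for (comp in compartments) {
    s <- tapply(records$fpkm[records$compartment == comp],
                records$locus_id[records$compartment == comp], sum)
    out[[comp]] <- as.numeric(s[match(loci, names(s))])
    out[[comp]][is.na(out[[comp]])] <- 0
  }
  class(out) <- c("locus_expression", "data.frame")
  attr(out, "compartments") <- compartments
  out
}

#' Subcellular localization profile
#'
#' Adds per-compartment fractions and the dominant compartment to a locus
#' expression table. Ties go to the compartment listed first in the
#' configured order; a locus with zero total expression has `NA` fractions
#' and an undefined (NA) dominant compartment.
#'
#' @param expr A `locus_expression` from [aggregate_locus_fpkm()].
#' @param compartments Compartment order used for tie-breaking; defaults to
#'   the order stored on `expr`.
#' @return `expr` with added columns `total`, `frac_<compartment>` and
#'   `dominant`.
#' @export
localization_profile <- function(expr, compartments = NULL) {
  comps <- compartments %||% attr(expr, "compartments")
  m <- as.matrix(expr[, comps, drop = FALSE])
  total <- rowSums(m)
  fr <- m / ifelse(total > 0, total, NA_real_)
  dominant <- comps[apply(m, 1L, which.max)]   # which.max: first max wins
  dominant[total == 0] <- NA_character_
  expr$total <- total
  for (j in seq_along(comps)) expr[[paste0("frac_", comps[j])]] <- fr[, j]
  expr$dominant <- dominant
  expr
}

#' Write a locus expression matrix (with fractions/dominant) as TSV
#' @param expr A `locus_expression`.
#' @param file Output path.
#' @export
write_locus_expression <- function(expr, file) {
  utils::write.table(as.data.frame(expr), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
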