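#' Pipeline configuration
#'
#' Collects every tunable knob of the discovery and expression layers in one
#' validated object. Precedence when running the CLI: command-line flag >
#' config file > these defaults.
#'
#' @param promoter_window Promoter window length upstream of the 5'-most
#'   TSS, bp. Default 1000.
#' @param coding_policy How transcripts with `unknown` coding status are
#'   treated when filtering for noncoding RNAs: `"strict"` excludes them,
#'   `"permissive"` keeps them.
#' @param min_overlap Minimum overlap (bp) for any classification flag.
#' @param excluded_class_codes Fragment class codes removed before locus
#'   FPKM aggregation (default intronic `i` and pre-mRNA `e`).
#' @param reference_gene qPCR normalisation reference (default PGK1).
#' @param alpha Significance level for reporting (default 0.05).
#' @param concordance_tau Correlation threshold for concordance calls.
#' @param efficiency Assumed PCR amplification efficiency (fold per cycle).
#' @param compartments Subcellular compartment set, in tie-break order.
#' @param min_assay_length Minimum qPCR assay region length, bp.
#' @param seed Optional integer seed recorded for simulation runs.
#' @return A list of class `nat_config`.
#' @export
nat_config <- function(promoter_window = 1000,
                       coding_policy = c("strict", "permissive"),
                       min_overlap = 1,
                       excluded_class_codes = c("i", "e"),
                       reference_gene = "PGK1",
                       alpha = 0.05,
                       concordance_tau = 0.3,
                       efficiency = 2,
                       compartments = c("cytoplasm", "nucleoplasm",
                                        "chromatin"),
                       min_assay_length = 60,
                       seed = NULL) {
  coding_policy <- match.arg(coding_policy)
  stopifnot(promoter_window >= 0, min_overlap >= 1,
            alpha > 0, alpha < 1, concordance_tau >= 0,
            efficiency > 1, min_assay_length > 0)
  structure(list(promoter_window = promoter_window,
                 coding_policy = coding_policy,
                 min_overlap = min_overlap,
                 excluded_class_codes = excluded_class_codes,
                 reference_gene = reference_gene,
                 alpha = alpha,
                 concordance_tau = concordance_tau,
                 efficiency = efficiency,
                 compartments = compartments,
                 min_assay_length = min_assay_length,
                 seed = seed),
            class = "nat_config")
}

#' Write a configuration to a JSON file
#' @param config A `nat_config`.
#' @param file Output path.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(file)
}

#' Read a configuration from a JSON file
#' @param file Path to a JSON file written by [write_config()].
#' @return A `nat_config`.
#' @export
read_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(nat_config, x[!vapply(x, is.null, logical(1))])
}

#' @export
print.nat_config <- function(x, ...) {
  cat("nat_config:\n")
  for (k in names(x))
    cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
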