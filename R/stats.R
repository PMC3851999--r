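#' Read a long-format qPCR Ct table
#'
#' TSV with header columns `sample`, `group`, `target`, `replicate`, `ct`.
#' Non-detects may be encoded as `ND`, `NA` or an empty field; they are kept
#' as rows with `nondetect = TRUE` rather than as fake numbers.
#'
#' @param file Path to the TSV.
#' @return data.frame with numeric `ct` (NA for non-detects) and logical
#'   `nondetect`.
#' @export
read_ct_table <- function(file) {
  if (!file.exists(file)) stop("Ct table not found: ", file)
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = c(ct = "character"))
  need <- c("sample", "group", "target", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  raw <- trimws(df$ct)
  nd <- raw %in% c("", "ND", "NA", "nd")
  ct <- suppressWarnings(as.numeric(raw))
  if (any(!nd & (!is.finite(ct) | ct <= 0)))
    stop("Ct values must be finite and positive (or ND)")
  df$ct <- ifelse(nd, NA_real_, ct)
  df$nondetect <- nd
  df
}

#' Relative expression by the delta-Ct method
#'
#' For each sample x target, technical replicates are averaged first; the
#' relative expression is `efficiency^-(meanCt_target - meanCt_reference)`
#' against the reference gene measured in the same sample (default PGK1,
#' efficiency 2 giving the classic 2^-dCt). A sample x target with no finite
#' replicate is a non-detect and yields an undefined value with a reason.
#'
#' @param ct_table data.frame from [read_ct_table()] (columns sample, group,
#'   target, ct).
#' @param reference Reference target name (default `"PGK1"`).
#' @param efficiency Amplification efficiency, fold per cycle (default 2).
#' @return data.frame: sample, group, target, mean_ct, delta_ct, rel_expr,
#'   reason (NA unless undefined). Reference rows are not returned.
#' @export
relative_expression <- function(ct_table, reference = "PGK1",
                                efficiency = 2) {
  stopifnot(efficiency > 1)
  if (!reference %in% ct_table$target)
    stop("reference target '", reference, "' absent from Ct table")
  agg <- stats::aggregate(ct ~ sample + group + target, data = ct_table,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$ct[!is.finite(agg$ct)] <- NA_real_
  ref <- agg[agg$target == reference, c("sample", "ct")]
  out <- agg[agg$target != reference, , drop = FALSE]
  names(out)[names(out) == "ct"] <- "mean_ct"
  out$ref_ct <- ref$ct[match(out$sample, ref$sample)]
  out$delta_ct <- out$mean_ct - out$ref_ct
  out$rel_expr <- efficiency^(-out$delta_ct)
  out$reason <- ifelse(is.na(out$mean_ct), "target non-detect",
                ifelse(is.na(out$ref_ct), "reference non-detect",
                       NA_character_))
  out$rel_expr[!is.na(out$reason)] <- NA_real_
  out$ref_ct <- NULL
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA across groups (e.g. brain regions) followed
#' by Tukey's honestly-significant-difference test on all group pairs, using
#' the studentized range distribution. The degenerate all-identical input
#' (zero total sum of squares) is reported as F = 0, p = 1.
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length as `values`.
#' @return List of class `comparison_result`: `statistic` (F), `p_value`,
#'   `df` (between, within), `method`, and `pairwise` (data.frame: contrast,
#'   diff, lwr, upr, p_adj).
#' @export
region_comparison <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  n_by <- table(groups)
  if (length(n_by) < 2L) stop("need at least two groups")
  small <- names(n_by)[n_by < 2L]
  if (length(small)) stop("group(s) with fewer than 2 values: ",
                          paste(small, collapse = ", "))
  if (sum((values - mean(values))^2) == 0) {
    combs <- utils::combn(sort(unique(groups)), 2L)
    pw <- data.frame(contrast = paste(combs[2L, ], combs[1L, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1)
    return(structure(list(statistic = 0, p_value = 1,
                          df = c(length(n_by) - 1L,
                                 length(values) - length(n_by)),
                          method = "one-way ANOVA + Tukey HSD",
                          pairwise = pw), class = "comparison_result"))
  }
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pw <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(statistic = tab["g", "F value"],
                 p_value = tab["g", "Pr(>F)"],
                 df = c(tab["g", "Df"], tab["Residuals", "Df"]),
                 method = "one-way ANOVA + Tukey HSD",
                 pairwise = pw), class = "comparison_result")
}

#' Two-sample t test (case vs control)
#'
#' Two-sided Student's t test assuming equal variances by default (Welch
#' available via `var_equal = FALSE`). Degenerate zero-variance inputs use
#' the documented convention: equal means give t = 0, p = 1; unequal means
#' give infinite t and p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (classic Student's t).
#' @return List of class `comparison_result`: `statistic` (t), `p_value`,
#'   `df`, `method`.
#' @export
two_group_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          p_value = if (eq) 1 else 0,
                          df = length(a) + length(b) - 2L,
                          method = "two-sample t test"),
                     class = "comparison_result"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 method = if (var_equal) "two-sample t test (equal variance)"
                          else "Welch two-sample t test"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey-adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Pearson correlation between paired sense and antisense expression
#'
#' @param sense,antisense Paired numeric vectors (same samples), length >= 3.
#' @return List: `estimate` (r), `p_value` (two-sided, t transform), `n`,
#'   `reason` (non-NULL when undefined, e.g. zero variance).
#' @export
sense_antisense_correlation <- function(sense, antisense) {
  if (length(sense) != length(antisense))
    stop("sense and antisense vectors must be paired (equal length)")
  if (length(sense) < 3L) stop("need at least 3 pairs")
  if (stats::var(sense) == 0 || stats::var(antisense) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_, n = length(sense),
                reason = "zero variance in one vector"))
  ht <- stats::cor.test(sense, antisense, method = "pearson")
  list(estimate = unname(ht$estimate), p_value = ht$p.value,
       n = length(sense), reason = NULL)
}

#' Label a sense-antisense pair concordant or discordant across groups
#'
#' Concordant when the most-expressed group matches for sense and antisense
#' (and, when a correlation is supplied, r > tau); discordant when the
#' most-expressed groups differ (and, when supplied, r < -tau); otherwise
#' indeterminate. Flat profiles (no variation in either vector) are
#' indeterminate.
#'
#' @param sense_by_group,antisense_by_group Named numeric vectors of group
#'   means over the same groups (>= 2 groups).
#' @param r Optional Pearson correlation of the paired per-sample values.
#' @param tau Correlation threshold (default 0.3).
#' @return `"concordant"`, `"discordant"` or `"indeterminate"`.
#' @export
concordance_label <- function(sense_by_group, antisense_by_group, r = NULL,
                              tau = 0.3) {
  gs <- names(sense_by_group)
  if (is.null(gs) || length(gs) < 2L ||
      !setequal(gs, names(antisense_by_group)))
    stop("need the same named groups (>= 2) for sense and antisense")
  antisense_by_group <- antisense_by_group[gs]
  if (diff(range(sense_by_group)) == 0 ||
      diff(range(antisense_by_group)) == 0)
    return("indeterminate")
  same_max <- gs[which.max(sense_by_group)] ==
    gs[which.max(antisense_by_group)]
  if (same_max && (is.null(r) || r > tau)) return("concordant")
  if (!same_max && (is.null(r) || r < -tau)) return("discordant")
  "indeterminate"
}
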