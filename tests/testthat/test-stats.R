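ct_rows <- function(sample, group, target, cts) data.frame(
  sample = sample, group = group, target = target,
  replicate = seq_along(cts), ct = cts, stringsAsFactors = FALSE)

test_that("delta-Ct relative expression averages replicates first", {
  ct <- rbind(ct_rows("s1", "PFC", "NAT1", c(25, 25, 25)),
              ct_rows("s1", "PFC", "PGK1", c(20, 20, 20)),
              ct_rows("s2", "PFC", "NAT1", c(24.9, 25.0, 25.1)),
              ct_rows("s2", "PFC", "PGK1", c(20, 20, 20)),
              ct_rows("s3", "PFC", "NAT1", c(21, 21, 21)),
              ct_rows("s3", "PFC", "PGK1", c(21, 21, 21)))
  rel <- relative_expression(ct)
  v <- setNames(rel$rel_expr, rel$sample)
  expect_equal(unname(v["s1"]), 2^-5)
  expect_equal(unname(v["s2"]), 2^-5)        # mean Ct 25 exactly
  expect_equal(unname(v["s3"]), 1)           # target == reference
  # efficiency knob changes the base
  rel15 <- relative_expression(ct, efficiency = 1.5)
  expect_equal(rel15$rel_expr[rel15$sample == "s1"], 1.5^-5)
})

test_that("non-detects yield undefined relative expression with a reason", {
  ct <- rbind(ct_rows("s1", "PFC", "NAT1", c(NA, NA, NA)),
              ct_rows("s1", "PFC", "PGK1", c(20, 20, 20)),
              ct_rows("s2", "PFC", "NAT1", c(25, NA, 25)),
              ct_rows("s2", "PFC", "PGK1", c(20, 20, 20)))
  rel <- relative_expression(ct)
  expect_true(is.na(rel$rel_expr[rel$sample == "s1"]))
  expect_equal(rel$reason[rel$sample == "s1"], "target non-detect")
  # partial non-detect: remaining replicates are averaged
  expect_equal(rel$rel_expr[rel$sample == "s2"], 2^-5)
})

test_that("Ct tables round-trip through TSV including ND markers", {
  sim <- simulate_ct_table(list(T1 = c(PFC = 26, STG = 26, CER = 24)),
                           seed = 8)
  sim$ct$ct[1] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(sim$ct, f)
  back <- read_ct_table(f)
  expect_true(back$nondetect[1])
  expect_equal(back$ct[-1], sim$ct$ct[-1], tolerance = 1e-8)
  expect_error(read_ct_table(withr::local_tempfile(lines =
    "sample\tgroup\ttarget\treplicate\tct\ns\tg\tt\t1\t-3")), "positive")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  # by hand: group means 2,3,4; grand mean 3; SSB = 3*(1+0+1) = 6, df 2;
  # SSW = 2+2+2 = 6, df 6; F = (6/2)/(6/6) = 3; p = P(F_{2,6} > 3)
  cmp <- region_comparison(vals, grp)
  expect_equal(cmp$statistic, 3, tolerance = 1e-9)
  expect_equal(cmp$p_value, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(cmp$df, c(2, 6))
  expect_equal(nrow(cmp$pairwise), 3L)
})

test_that("degenerate and invalid ANOVA inputs follow the documented conventions", {
  cmp <- region_comparison(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$pairwise$p_adj == 1))
  expect_error(region_comparison(c(1, 2, 3), c("a", "a", "b")),
               "fewer than 2")
  expect_error(region_comparison(1:4, rep("a", 4)), "two groups")
})

test_that("Tukey-adjusted p values are never below raw pairwise p values", {
  set.seed(15)
  for (k in 1:5) {
    vals <- rnorm(21, mean = rep(c(0, 0.5, 1), each = 7))
    grp <- rep(c("g1", "g2", "g3"), each = 7)
    cmp <- region_comparison(vals, grp)
    raw <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    for (i in seq_len(nrow(cmp$pairwise))) {
      pr <- strsplit(cmp$pairwise$contrast[i], "-", fixed = TRUE)[[1]]
      rawp <- if (!is.na(raw[pr[1], pr[2]])) raw[pr[1], pr[2]]
              else raw[pr[2], pr[1]]
      expect_gte(cmp$pairwise$p_adj[i] + 1e-12, rawp)
    }
  }
})

test_that("Student's t test matches the closed form and its conventions", {
  res <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.6742346, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(res$statistic, df = 4), tolerance = 1e-9)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(res$df, 4)
  # identical groups
  same <- two_group_test(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  # zero variance, different means
  diffm <- two_group_test(c(1, 1), c(2, 2))
  expect_equal(diffm$p_value, 0)
  expect_true(is.infinite(diffm$statistic))
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("F = t^2 for two groups", {
  set.seed(4)
  for (k in 1:10) {
    a <- rnorm(6); b <- rnorm(8, 0.5)
    f <- region_comparison(c(a, b), rep(c("x", "y"), c(6, 8)))$statistic
    t <- two_group_test(a, b)$statistic
    expect_equal(f, t^2, tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches hand computation and its invariances", {
  # x = 1..4, y = (2,1,4,3): cov = 1.333.., sd_x = sd_y = 1.2910 -> r = 0.6
  res <- sense_antisense_correlation(1:4, c(2, 1, 4, 3))
  expect_equal(res$estimate, 0.6, tolerance = 1e-9)
  expect_equal(res$p_value, 0.4, tolerance = 1e-9)
  expect_equal(sense_antisense_correlation(1:5, 6 - (1:5))$estimate, -1)
  # affine rescaling with positive slope leaves r unchanged
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- sense_antisense_correlation(x, y)$estimate
  expect_equal(sense_antisense_correlation(3 * x + 7, y)$estimate, r0,
               tolerance = 1e-9)
  expect_equal(sense_antisense_correlation(x, 0.1 * y - 2)$estimate, r0,
               tolerance = 1e-9)
  # joint shuffling of pairs leaves r unchanged
  p <- sample(12)
  expect_equal(sense_antisense_correlation(x[p], y[p])$estimate, r0,
               tolerance = 1e-9)
  zv <- sense_antisense_correlation(rep(1, 5), rnorm(5))
  expect_true(is.na(zv$estimate))
  expect_match(zv$reason, "zero variance")
  expect_error(sense_antisense_correlation(1:3, 1:4), "paired")
})

test_that("concordance labels follow arg-max agreement and the correlation gate", {
  # same region is maximal for both: concordant
  expect_equal(concordance_label(c(PFC = 1, STG = 1, CER = 3),
                                 c(PFC = 0.2, STG = 0.1, CER = 0.9)),
               "concordant")
  # maxima in different regions: discordant
  expect_equal(concordance_label(c(PFC = 3, STG = 2, CER = 1),
                                 c(PFC = 0.1, STG = 0.2, CER = 0.9)),
               "discordant")
  # flat profiles are indeterminate
  expect_equal(concordance_label(c(a = 1, b = 1), c(a = 2, b = 2)),
               "indeterminate")
  # correlation gate: matching maxima but negative r -> indeterminate
  expect_equal(concordance_label(c(a = 1, b = 2), c(a = 1, b = 2), r = -0.9),
               "indeterminate")
  expect_equal(concordance_label(c(a = 1, b = 2), c(a = 1, b = 2), r = 0.9),
               "concordant")
  expect_equal(concordance_label(c(a = 1, b = 2), c(a = 2, b = 1), r = -0.9),
               "discordant")
  expect_error(concordance_label(c(a = 1, b = 2), c(a = 1, c = 2)),
               "same named groups")
})
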