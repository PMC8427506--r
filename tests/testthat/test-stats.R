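test_that("ttest_unpaired agrees with the pooled t reference", {
  set.seed(7)
  for (r in 1:20) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- ttest_unpaired(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic))
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value)
  }
  got <- ttest_unpaired(c(1, 2, NA), c(3, 4, 5))
  expect_identical(got$n, c(2L, 3L))
  expect_error(ttest_unpaired(1, c(2, 3)), "at least 2")
})

test_that("degenerate zero-variance groups are flagged, not crashed", {
  same <- ttest_unpaired(c(2, 2, 2), c(2, 2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_false(same$degenerate)
  diff <- ttest_unpaired(c(2, 2, 2), c(3, 3))
  expect_true(diff$degenerate)
  expect_true(is.infinite(diff$t))
  expect_true(is.na(diff$p))
})

test_that("p_from_t is the two-sided Student tail", {
  expect_equal(p_from_t(2.0, 10), 2 * pt(-2, 10))
  expect_equal(p_from_t(-2.0, 10), p_from_t(2.0, 10))   # sign ignored
  expect_equal(p_from_t(0, 5), 1)
  expect_error(p_from_t(1, 0.5))
})

test_that("per-class chi-square equals the uncorrected Pearson reference", {
  wt <- c(SB = 13, WB = 35, RF = 17)
  as_ <- c(SB = 10, WB = 40, RF = 16)
  got <- chisq_distribution(wt, as_)
  expect_identical(got$class, c("SB", "WB", "RF"))
  for (i in 1:3) {
    cl <- got$class[i]
    tab <- rbind(c(wt[[cl]], sum(wt) - wt[[cl]]),
                 c(as_[[cl]], sum(as_) - as_[[cl]]))
    ref <- chisq.test(tab, correct = FALSE)
    expect_equal(got$chi2[i], unname(ref$statistic))
    expect_equal(got$p[i], ref$p.value)
    expect_equal(got$df[i], 1)
  }
  omni <- chisq_distribution(wt, as_, per_class = FALSE)
  ref <- chisq.test(rbind(wt, as_), correct = FALSE)
  expect_equal(omni$chi2, unname(ref$statistic))
  expect_equal(omni$df, 2)
})

test_that("a zero-count class is degenerate, not an error", {
  got <- chisq_distribution(c(SB = 0, WB = 10), c(SB = 0, WB = 12))
  expect_true(got$degenerate[1])
  expect_true(is.na(got$p[1]))
  # WB vs rest is 10/0 and 12/0 -> an expected cell is zero -> degenerate too
  expect_true(got$degenerate[2])
})

test_that("mixed ANOVA reproduces the aov split-plot decomposition", {
  set.seed(11)
  for (r in 1:5) {
    n <- sample(4:8, 1)
    s <- sample(3:6, 1)
    g <- rep(c("WT", "AS"), each = n)
    Y <- matrix(rnorm(2 * n * s), 2 * n, s,
                dimnames = list(NULL, paste0(seq_len(s) * 50)))
    Y[g == "AS", ] <- Y[g == "AS", ] + 0.5
    got <- anova2_rm(Y, g)
    long <- data.frame(y = as.vector(Y),
                       subj = factor(rep(seq_len(2 * n), s)),
                       geno = factor(rep(g, s)),
                       step = factor(rep(colnames(Y), each = 2 * n)))
    fit <- summary(stats::aov(y ~ geno * step + Error(subj/step), data = long))
    up <- fit[["Error: subj"]][[1]]
    dn <- fit[["Error: subj:step"]][[1]]
    row_of <- function(df, nm, col) df[trimws(rownames(df)) == nm, col]
    expect_equal(got$genotype$F, row_of(up, "geno", "F value"), tolerance = 1e-8)
    expect_equal(got$genotype$p, row_of(up, "geno", "Pr(>F)"), tolerance = 1e-8)
    expect_equal(got$step$F, row_of(dn, "step", "F value"), tolerance = 1e-8)
    expect_equal(got$interaction$F, row_of(dn, "geno:step", "F value"),
                 tolerance = 1e-8)
    expect_equal(got$interaction$p, row_of(dn, "geno:step", "Pr(>F)"),
                 tolerance = 1e-8)
    expect_equal(got$genotype$df2, 2 * n - 2)
    expect_equal(got$interaction$df1, s - 1)
  }
})

test_that("post hoc battery is per-step pooled t with Bonferroni cap", {
  set.seed(12)
  g <- rep(c("WT", "AS"), each = 6)
  Y <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0(1:6 * 50)))
  got <- anova2_rm(Y, g)
  expect_identical(nrow(got$posthoc), 6L)
  for (i in 1:6) {
    ref <- t.test(Y[g == "AS", i], Y[g == "WT", i], var.equal = TRUE)
    expect_equal(abs(got$posthoc$t[i]), abs(unname(ref$statistic)))
    expect_equal(got$posthoc$p_raw[i], ref$p.value)
    expect_equal(got$posthoc$p_bonferroni[i], min(1, 6 * ref$p.value))
  }
  expect_true(all(got$posthoc$p_bonferroni <= 1))
})

test_that("cells with missing steps are dropped with a message", {
  g <- rep(c("WT", "AS"), each = 4)
  Y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("50", "100", "150")))
  Y[3, 2] <- NA
  expect_message(got <- anova2_rm(Y, g), "dropped")
  expect_identical(sum(got$n_per_group), 7L)
})

test_that("binned KS agrees with ks.test on shared binned data", {
  set.seed(13)
  x <- pmin(pmax(rlnorm(400, log(20), 0.5), 6), 80)
  y <- pmin(pmax(rlnorm(500, log(25), 0.5), 6), 80)
  got <- ks_binned(binned_cdf(x, "amplitude"), binned_cdf(y, "amplitude"))
  ref <- suppressWarnings(ks.test(x, y))
  # binned D can differ from the exact D by at most the within-bin mass
  expect_lt(abs(got$D - unname(ref$statistic)), 0.02)
  expect_gt(got$p, 0)
  expect_lte(got$p, 1)
  # identical samples -> D = 0, p = 1
  same <- ks_binned(binned_cdf(x, "amplitude"), binned_cdf(x, "amplitude"))
  expect_identical(same$D, 0)
  expect_identical(same$p, 1)
  expect_error(ks_binned(binned_cdf(x, "amplitude"), binned_cdf(y, "iei")),
               "edges")
})

test_that("distribution_table reports integer percentages per genotype", {
  labels <- data.frame(
    genotype = c(rep("WT", 6), rep("AS", 4)),
    label = c("SB", "SB", "WB", "WB", "WB", "RF", "WB", "RF", "RF", NA))
  tab <- distribution_table(labels)
  wt <- tab[tab$genotype == "WT", ]
  expect_identical(wt$class, c("SB", "WB", "RF"))
  expect_identical(wt$n, c(2L, 3L, 1L))
  expect_identical(wt$percent, round(100 * c(2, 3, 1) / 6))
  expect_identical(unique(wt$total), 6L)
  as_ <- tab[tab$genotype == "AS", ]
  expect_identical(sum(as_$n), 3L)          # NA label excluded
  expect_identical(unique(as_$total), 3L)
})
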