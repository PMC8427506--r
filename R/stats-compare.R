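#' Two-sided unpaired Student's t test
#'
#' Pooled-variance (classical Student) t test, the group-comparison test
#' used for all per-cell intrinsic and synaptic measures.  `NA` values are
#' dropped.
#'
#' @param x,y Numeric samples (each of length >= 2 after NA removal).
#' @return An object of class `ttest_result`: `t`, `df`, `p`, per-group
#'   `mean`, `sem`, `n`, and a `degenerate` flag set when the pooled
#'   variance is zero.
#' @export
ttest_unpaired <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  df <- length(x) + length(y) - 2
  if (stats::var(x) + stats::var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(t = if (equal) 0 else Inf, df = df, p = if (equal) 1 else NA_real_,
                degenerate = !equal)
  } else {
    tt <- t.test(x, y, var.equal = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE)
  }
  res$mean <- c(mean(x), mean(y))
  res$sem <- c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y)))
  res$n <- c(length(x), length(y))
  structure(res, class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g; means %.3g +/- %.2g (n=%d) vs %.3g +/- %.2g (n=%d)\n",
              x$df, x$t, x$p, x$mean[1], x$sem[1], x$n[1],
              x$mean[2], x$sem[2], x$n[2]))
  invisible(x)
}

#' Two-sided p-value from a t statistic
#'
#' @param t t statistic (sign ignored).
#' @param df Degrees of freedom (>= 1).
#' @return Two-sided tail probability.
#' @export
p_from_t <- function(t, df) {
  stopifnot(all(df >= 1))
  2 * pt(-abs(t), df)
}

#' Chi-square tests on the class distribution
#'
#' Compares the SB/WB/RF composition between genotypes.  In `per_class`
#' mode each class is tested with a 2x2 Pearson chi-square (class vs rest
#' by genotype, df = 1, no continuity correction unless requested); the
#' omnibus mode tests the full 3x2 table (df = 2).
#'
#' @param counts_wt,counts_as Named counts per class (e.g.
#'   `c(SB = 13, WB = 35, RF = 17)`).
#' @param per_class One test per class (default) or a single omnibus test.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return A data frame: `class` (or `"omnibus"`), `chi2`, `df`, `p`,
#'   `degenerate` (TRUE when an expected cell count is zero).
#' @export
chisq_distribution <- function(counts_wt, counts_as, per_class = TRUE,
                               correct = FALSE) {
  stopifnot(sum(counts_wt) > 0, sum(counts_as) > 0,
            identical(names(counts_wt), names(counts_as)))
  one <- function(tab, label) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    degen <- any(expected == 0)
    if (degen) return(data.frame(class = label, chi2 = NA_real_,
                                 df = NA_real_, p = NA_real_, degenerate = TRUE))
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    data.frame(class = label, chi2 = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value, degenerate = FALSE)
  }
  if (per_class) {
    out <- lapply(names(counts_wt), function(cl) {
      tab <- rbind(WT = c(counts_wt[[cl]], sum(counts_wt) - counts_wt[[cl]]),
                   AS = c(counts_as[[cl]], sum(counts_as) - counts_as[[cl]]))
      one(tab, cl)
    })
    do.call(rbind, out)
  } else {
    one(rbind(WT = unlist(counts_wt), AS = unlist(counts_as)), "omnibus")
  }
}

#' Mixed-design (repeated-measures two-way) ANOVA on f-I responses
#'
#' Between-subject factor: genotype; within-subject factor: current step.
#' The classical split-plot decomposition is used: the genotype effect is
#' tested against subjects-within-genotype, the step and interaction
#' effects against the subject-by-step residual.  No sphericity correction
#' is applied.  Per-step unpaired comparisons with Bonferroni correction
#' (p multiplied by the number of steps, capped at 1) are returned as the
#' post hoc battery.
#'
#' @param responses Numeric matrix or data frame, one row per cell, one
#'   column per current step (column names are the step labels).  Cells
#'   with any missing step are dropped with a message.
#' @param genotype Factor/character of length `nrow(responses)`.
#' @param steps Optional subset of column names (e.g. to restrict the
#'   tested step range).
#' @return An object of class `anova2_rm_result` with `genotype`
#'   (`F`, `df1`, `df2`, `p`), `step`, `interaction`, and `posthoc`
#'   (data frame: step, t, df, p_raw, p_bonferroni).
#' @export
anova2_rm <- function(responses, genotype, steps = NULL) {
  Y <- as.matrix(responses)
  g <- as.factor(genotype)
  if (!is.null(steps)) Y <- Y[, as.character(steps), drop = FALSE]
  complete <- stats::complete.cases(Y)
  if (!all(complete)) {
    message(sum(!complete), " cell(s) dropped for missing steps")
    Y <- Y[complete, , drop = FALSE]
    g <- droplevels(g[complete])
  }
  if (any(table(g) < 2)) stop("need at least 2 cells per genotype")
  N <- nrow(Y)
  s <- ncol(Y)
  ng <- nlevels(g)
  Tg <- tapply(rowSums(Y), g, sum)
  n_g <- tabulate(g)
  Ti <- rowSums(Y)
  Tj <- colSums(Y)
  Tt <- sum(Y)
  CT <- Tt^2 / (N * s)
  ss_total <- sum(Y^2) - CT
  ss_between_subj <- sum(Ti^2) / s - CT
  ss_geno <- sum(Tg^2 / (s * n_g)) - CT
  ss_subj_within <- ss_between_subj - ss_geno
  ss_step <- sum(Tj^2) / N - CT
  Tgj <- rowsum(Y, g)                      # group-by-step totals
  ss_gxs <- sum(Tgj^2 / n_g) - CT - ss_geno - ss_step
  ss_resid <- ss_total - ss_between_subj - ss_step - ss_gxs
  df_geno <- ng - 1
  df_sw <- N - ng
  df_step <- s - 1
  df_gxs <- df_geno * df_step
  df_resid <- df_step * df_sw
  Fg <- (ss_geno / df_geno) / (ss_subj_within / df_sw)
  Fs <- (ss_step / df_step) / (ss_resid / df_resid)
  Fi <- (ss_gxs / df_gxs) / (ss_resid / df_resid)
  post <- do.call(rbind, lapply(colnames(Y), function(cn) {
    tt <- ttest_unpaired(Y[g == levels(g)[1], cn], Y[g == levels(g)[2], cn])
    data.frame(step = cn, t = tt$t, df = tt$df, p_raw = tt$p,
               p_bonferroni = min(1, tt$p * s))
  }))
  structure(list(
    genotype = list(F = Fg, df1 = df_geno, df2 = df_sw,
                    p = pf(Fg, df_geno, df_sw, lower.tail = FALSE)),
    step = list(F = Fs, df1 = df_step, df2 = df_resid,
                p = pf(Fs, df_step, df_resid, lower.tail = FALSE)),
    interaction = list(F = Fi, df1 = df_gxs, df2 = df_resid,
                       p = pf(Fi, df_gxs, df_resid, lower.tail = FALSE)),
    posthoc = post, n_per_group = as.vector(table(g)), steps = colnames(Y)),
    class = "anova2_rm_result")
}

#' @export
print.anova2_rm_result <- function(x, ...) {
  cat(sprintf("mixed ANOVA: genotype F(%d,%d) = %.3f, p = %.4g; interaction F(%d,%d) = %.3f, p = %.4g\n",
              x$genotype$df1, x$genotype$df2, x$genotype$F, x$genotype$p,
              x$interaction$df1, x$interaction$df2, x$interaction$F,
              x$interaction$p))
  invisible(x)
}

#' Two-sample KS test on binned cumulative distributions
#'
#' D is the largest absolute difference between the two binned CDFs over
#' the shared edges; the p-value uses the asymptotic two-sample
#' Kolmogorov distribution with effective n = n1 n2 / (n1 + n2).
#'
#' @param cdf1,cdf2 [binned_cdf()] objects with identical edges.
#' @param n1,n2 Underlying sample sizes; default to the in-range counts
#'   stored in the CDFs.
#' @return An object of class `ks_result`: `D`, `p`.
#' @export
ks_binned <- function(cdf1, cdf2, n1 = cdf1$n, n2 = cdf2$n) {
  if (!isTRUE(all.equal(cdf1$edges, cdf2$edges)))
    stop("binned CDFs must share identical edges")
  D <- max(abs(cdf1$cumfrac - cdf2$cumfrac))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  if (D <= 0) p <- 1 else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  structure(list(D = D, p = p, n_eff = ne), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS D = %.4f, p = %.4g\n", x$D, x$p))
  invisible(x)
}

#' Class-distribution table with percentages
#'
#' Counts cells per class and genotype and reports integer-rounded
#' percentages of each genotype's total, the composition summary of a
#' classified cohort.
#'
#' @param labels Data frame with columns `genotype` and `label`
#'   (e.g. built from [classify_cell()] results); unclassified cells
#'   (`NA` label) are excluded.
#' @param classes Class order for the table.
#' @return A data frame: `genotype`, `class`, `n`, `percent`, `total`.
#' @export
distribution_table <- function(labels, classes = c("SB", "WB", "RF")) {
  labels <- labels[!is.na(labels$label), , drop = FALSE]
  out <- do.call(rbind, lapply(unique(labels$genotype), function(g) {
    sub <- labels[labels$genotype == g, ]
    n <- vapply(classes, function(cl) sum(sub$label == cl), 0L)
    data.frame(genotype = g, class = classes, n = n,
               percent = round(100 * n / nrow(sub)), total = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}
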