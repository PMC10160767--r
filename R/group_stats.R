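# Channel-level activation inference. Effects enter as [subject x channel]
# matrices of windowed HbO changes (uM); every test is the textbook t
# statistic computed explicitly (and cross-checked against stats::t.test in
# the test suite). Degenerate zero-variance cases are reported with a flag
# rather than NaN.

one_sample_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    list(t = if (m == 0) 0 else sign(m) * Inf,
         p = if (m == 0) 1 else 0, df = n - 1, degenerate = TRUE)
  } else {
    tt <- m / (s / sqrt(n))
    list(t = tt, p = 2 * stats::pt(-abs(tt), n - 1), df = n - 1,
         degenerate = FALSE)
  }
}

welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = na + nb - 2,
                degenerate = TRUE))
  }
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, degenerate = FALSE)
}

activation_frame <- function(channels, effect, tests, contrast, alpha,
                             n, adjust) {
  p <- vapply(tests, `[[`, numeric(1), "p")
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  data.frame(channel = channels,
             chromophore = "HbO",
             contrast = contrast,
             effect = effect,
             t_statistic = vapply(tests, `[[`, numeric(1), "t"),
             p_value = p,
             df = vapply(tests, `[[`, numeric(1), "df"),
             n = n,
             significant = p < alpha,
             degenerate = vapply(tests, `[[`, logical(1), "degenerate"),
             row.names = NULL)
}

check_effects <- function(E, min_n = 2) {
  E <- as.matrix(E)
  if (nrow(E) < min_n)
    stop("at least ", min_n, " subjects are required")
  if (is.null(colnames(E))) colnames(E) <- sprintf("ch%02d", seq_len(ncol(E)))
  E
}

#' One-day activation versus baseline
#'
#' One-sample two-sided t-test, per channel, of the subjects' windowed HbO
#' effects against zero.
#'
#' @param effects numeric matrix `[subject x channel]` of windowed effects
#'   for one day (uM).
#' @param alpha significance level (default 0.05).
#' @param contrast label carried into the result.
#' @param adjust multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` by default (channelwise uncorrected inference; set `"BH"` for
#'   Benjamini-Hochberg).
#' @return data frame with one row per channel: effect (mean), t, p, n,
#'   significance flag and a degeneracy flag for zero-variance inputs.
#' @export
day_vs_baseline <- function(effects, alpha = 0.05,
                            contrast = "day_vs_baseline", adjust = "none") {
  E <- check_effects(effects)
  tests <- lapply(seq_len(ncol(E)), function(j) one_sample_t(E[, j]))
  activation_frame(colnames(E), colMeans(E), tests, contrast, alpha,
                   nrow(E), adjust)
}

#' Paired contrast between two training days
#'
#' Paired t-test on the per-subject differences of windowed effects; rows of
#' the two matrices must describe the same subjects in the same order.
#' Positive effects mean the second day exceeds the first (day 15 > day 1).
#'
#' @param effects_day1,effects_day15 `[subject x channel]` effect matrices.
#' @param alpha significance level.
#' @param adjust multiple-testing adjustment (default `"none"`).
#' @return data frame as in [day_vs_baseline()].
#' @export
paired_day_contrast <- function(effects_day1, effects_day15, alpha = 0.05,
                                adjust = "none") {
  E1 <- check_effects(effects_day1)
  E15 <- check_effects(effects_day15)
  if (!identical(dim(E1), dim(E15)))
    stop("the two days must have matched subject sets")
  if (!is.null(rownames(E1)) && !is.null(rownames(E15)) &&
      !identical(rownames(E1), rownames(E15)))
    stop("unmatched subject sets between days")
  D <- E15 - E1
  tests <- lapply(seq_len(ncol(D)), function(j) one_sample_t(D[, j]))
  activation_frame(colnames(D), colMeans(D), tests, "day15_vs_day1", alpha,
                   nrow(D), adjust)
}

#' Split a cohort by final-day performance
#'
#' Threshold at the cohort mean of the final-day performance scores: subjects
#' at or above the mean are the good learners, subjects below it the weak
#' learners (ties go above).
#'
#' @param scores named numeric vector of final-day scores, one per subject.
#' @return list with `above` and `below` (subject names), and `threshold`.
#' @export
split_by_performance <- function(scores) {
  if (length(scores) < 2) stop("at least 2 subjects are required")
  if (is.null(names(scores))) names(scores) <- sprintf("subj%02d",
                                                       seq_along(scores))
  thr <- mean(scores)
  if (all(scores == scores[1]))
    stop("degenerate split: all final-day scores are equal")
  list(above = names(scores)[scores >= thr],
       below = names(scores)[scores < thr],
       threshold = thr)
}

#' Independent-groups contrast (good versus weak learners)
#'
#' Welch two-sample t-test per channel; positive effects mean group A exceeds
#' group B.
#'
#' @param effects_a,effects_b `[subject x channel]` effect matrices for the
#'   two groups (e.g. good and weak learners).
#' @param alpha significance level.
#' @param adjust multiple-testing adjustment (default `"none"`).
#' @return data frame as in [day_vs_baseline()].
#' @export
group_contrast <- function(effects_a, effects_b, alpha = 0.05,
                           adjust = "none") {
  A <- check_effects(effects_a)
  B <- check_effects(effects_b)
  if (ncol(A) != ncol(B)) stop("groups must share the channel set")
  tests <- lapply(seq_len(ncol(A)), function(j) welch_t(A[, j], B[, j]))
  activation_frame(colnames(A), colMeans(A) - colMeans(B), tests,
                   "groupA_vs_groupB", alpha, nrow(A) + nrow(B), adjust)
}

#' Repeated-measures comparison of performance scores
#'
#' Convenience wrapper: one-way repeated-measures ANOVA of per-subject scores
#' across periods (e.g. day 1, day 15, retention) with Bonferroni-adjusted
#' paired t-tests as post hoc contrasts. The paired contrasts are the tested
#' surface; the ANOVA is routine.
#'
#' @param scores numeric matrix `[subject x period]` of performance scores.
#' @return list with the ANOVA table (`anova`) and the pairwise paired
#'   t-tests (`pairwise`, Bonferroni-adjusted p-values).
#' @export
performance_anova <- function(scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("period%d", seq_len(ncol(scores)))
  df <- data.frame(
    score = as.vector(scores),
    period = factor(rep(colnames(scores), each = nrow(scores)),
                    levels = colnames(scores)),
    subject = factor(rep(seq_len(nrow(scores)), times = ncol(scores))))
  fit <- stats::aov(score ~ period + Error(subject / period), data = df)
  pw <- stats::pairwise.t.test(df$score, df$period, paired = TRUE,
                               p.adjust.method = "bonferroni")
  list(anova = summary(fit), pairwise = pw)
}
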