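#' Pearson correlation of a feature with symptom severity
#'
#' Correlates one pairwise feature's per-subject values with the ADOS
#' total severity score over the subjects that have a score. The
#' two-sided p-value uses the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution
#' with n - 2 degrees of freedom. At the screen's working point
#' (r = 0.32, n = 61) this p-value rounds to 0.01, which is how the
#' default screening threshold of [significance_screen()] is anchored.
#'
#' @param feature_values Numeric vector of per-subject feature values.
#' @param severity Numeric vector of ADOS total scores, same length.
#' @return List with elements `r`, `p` and `n`.
#' @export
correlate_with_severity <- function(feature_values, severity) {
  ok <- is.finite(feature_values) & is.finite(severity)
  x <- feature_values[ok]; y <- severity[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- cor(x, y)
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n)
}

#' Two-sided p-value for a Pearson correlation
#'
#' @param r Correlation coefficient(s) in (-1, 1).
#' @param n Number of paired observations (> 2).
#' @return Two-sided p-value(s) from the t distribution with n - 2 df.
#' @export
r_to_p <- function(r, n) {
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Severity correlation screen over a feature universe
#'
#' Correlates every pairwise feature with the ADOS total score and
#' flags the features whose absolute correlation reaches the
#' threshold. The default threshold |r| >= 0.32 corresponds to a
#' two-sided p-value of 0.01 at n = 61 scored subjects. No
#' multiple-testing correction is applied by default — the screen is a
#' raw-correlation filter; set `bh_fdr` to additionally report
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param X Subjects x features matrix (only subjects with a severity
#'   score).
#' @param index Feature universe data frame matching the columns of `X`.
#' @param severity ADOS totals, one per row of `X`.
#' @param threshold_r Absolute-correlation threshold in (0, 1).
#' @param bh_fdr If `TRUE`, add a `p_adj` column of BH-adjusted
#'   p-values (reported, not used for the `significant` flag).
#' @return A data frame of class `correlation_screen`: the feature
#'   index plus `r`, `p`, `significant`; attributes `threshold_r`,
#'   `n`, and `counts` (significant counts per modality and, for sMRI,
#'   per feature slab).
#' @export
significance_screen <- function(X, index, severity, threshold_r = 0.32,
                                bh_fdr = FALSE) {
  if (threshold_r <= 0 || threshold_r > 1) {
    stop("threshold_r must be in (0, 1]", call. = FALSE)
  }
  if (nrow(X) != length(severity)) {
    stop("severity length must match rows of X", call. = FALSE)
  }
  if (nrow(index) != ncol(X)) {
    stop("feature index does not match columns of X", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 scored subjects", call. = FALSE)
  r <- as.vector(cor(X, severity))
  r[is.na(r)] <- 0   # constant feature: no association, never significant
  p <- r_to_p(r, n)
  out <- cbind(index,
               data.frame(r = r, p = p,
                          significant = abs(r) >= threshold_r))
  if (bh_fdr) out$p_adj <- p.adjust(p, method = "BH")
  feats <- morphometric_features()
  per_slab <- if (any(index$modality == "sMRI")) {
    sm <- out[out$modality == "sMRI", ]
    counts <- vapply(seq_len(8L),
                     function(f) sum(sm$significant[sm$f == f]),
                     integer(1))
    stats::setNames(counts, feats)
  } else NULL
  attr(out, "threshold_r") <- threshold_r
  attr(out, "n") <- n
  attr(out, "counts") <- list(
    per_modality = tapply(out$significant, out$modality, sum),
    per_slab = per_slab
  )
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' @importFrom stats p.adjust setNames
NULL

#' Rank atlas areas by frequency among significant features
#'
#' Counts, for every atlas area, how many significant pairwise
#' features involve it (as either endpoint i or j), and sorts the
#' areas by descending count with ties broken by atlas order. This is
#' the area-frequency view of the severity screen: areas that
#' participate in many severity-correlated features rank first.
#'
#' @param screen A `correlation_screen` from [significance_screen()],
#'   or any data frame with columns `i`, `j`, `significant`.
#' @param atlas Atlas definition used to name the areas.
#' @return Data frame with `area` (index), `region` (name), `count`,
#'   sorted by descending count then atlas order.
#' @export
area_frequency_ranking <- function(screen, atlas = dk_atlas()) {
  validate_atlas(atlas)
  sig <- screen[screen$significant, , drop = FALSE]
  counts <- tabulate(c(sig$i, sig$j), nbins = 68L)
  out <- data.frame(area = seq_len(68L), region = atlas$name,
                    count = counts, stringsAsFactors = FALSE)
  out[order(-out$count, out$area), ]
}

#' Cohort demographic hypothesis tests
#'
#' Reproduces the standard cohort-description tests: a chi-squared
#' test (without continuity correction) of sex against diagnosis on
#' the 2 x 2 contingency table, a pooled-variance two-sample t-test of
#' age between diagnostic groups, and descriptive medians/ranges of
#' the ADOS scores where available.
#'
#' @param manifest A `cohort_manifest` from [read_cohort_manifest()]
#'   (or any data frame with `label`, `sex`, `age` and optional ADOS
#'   columns).
#' @return List with `sex_chi2` (`statistic`, `p`), `age_t`
#'   (`statistic`, `p`, `df`), and `ados_summary`.
#' @export
cohort_demographic_tests <- function(manifest) {
  lab <- factor(manifest$label, levels = c("TD", "ASD"))
  if (nlevels(droplevels(lab)) < 2L) {
    stop("both diagnostic classes must be present", call. = FALSE)
  }
  tab <- table(manifest$sex, lab)
  tab <- tab[rownames(tab) %in% c("M", "F"), , drop = FALSE]
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tt <- stats::t.test(age ~ lab, data = manifest, var.equal = TRUE)
  ados <- manifest$ados_total[!is.na(manifest$ados_total)]
  summarize <- function(x) {
    if (!length(x)) return(NULL)
    list(n = length(x), median = median(x), range = range(x))
  }
  list(
    sex_chi2 = list(statistic = unname(chi$statistic), p = chi$p.value),
    age_t = list(statistic = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter)),
    ados_summary = list(
      total = summarize(ados),
      sa = summarize(manifest$ados_sa[!is.na(manifest$ados_sa)]),
      rrb = summarize(manifest$ados_rrb[!is.na(manifest$ados_rrb)])
    )
  )
}

#' Demographic tests from per-subgroup summary moments
#'
#' Overload of [cohort_demographic_tests()] that accepts the
#' (count, mean, SD) summaries typically printed in a cohort table —
#' one row per diagnosis-by-sex subgroup — and reconstructs the exact
#' per-group age moments before running the same tests. Group means
#' are count-weighted subgroup means and group sums of squares combine
#' within-subgroup scatter `(n_k - 1) s_k^2` with between-subgroup
#' scatter `n_k (m_k - m)^2`, so the pooled two-sample t statistic is
#' identical to the raw-data computation.
#'
#' @param summaries Data frame with columns `label` (`ASD`/`TD`),
#'   `sex` (`M`/`F`), `n`, `age_mean`, `age_sd`.
#' @return List with `sex_chi2` and `age_t` as in
#'   [cohort_demographic_tests()].
#' @export
demographic_tests_from_moments <- function(summaries) {
  req <- c("label", "sex", "n", "age_mean", "age_sd")
  if (!all(req %in% names(summaries))) {
    stop("summaries must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("ASD", "TD") %in% summaries$label)) {
    stop("both diagnostic classes must be present", call. = FALSE)
  }
  groups <- lapply(split(summaries, summaries$label), function(g) {
    n <- sum(g$n)
    m <- sum(g$n * g$age_mean) / n
    ss <- sum((g$n - 1) * g$age_sd^2 + g$n * (g$age_mean - m)^2)
    list(n = n, mean = m, ss = ss)
  })
  a <- groups[["ASD"]]; t_ <- groups[["TD"]]
  df <- a$n + t_$n - 2
  sp2 <- (a$ss + t_$ss) / df
  tstat <- (a$mean - t_$mean) / sqrt(sp2 * (1 / a$n + 1 / t_$n))
  p_t <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)

  tab <- stats::xtabs(n ~ sex + label, data = summaries)
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_)^2 / exp_)
  p_chi <- pchisq(chi2, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                  lower.tail = FALSE)
  list(
    sex_chi2 = list(statistic = chi2, p = p_chi),
    age_t = list(statistic = tstat, p = p_t, df = df)
  )
}
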