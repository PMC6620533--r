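test_that("the screen threshold corresponds to p = 0.01 at n = 61", {
  # analytic working point of the severity screen
  p <- r_to_p(0.32, 61)
  expect_equal(round(p, 2), 0.01)
  expect_equal(p, 0.0119, tolerance = 0.01)
})

test_that("correlate_with_severity handles exact and degenerate inputs", {
  x <- seq_len(20)
  res <- correlate_with_severity(x, 2 * x + 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-20)
  expect_error(correlate_with_severity(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_with_severity(1:3, 1:3), "at least 4")
  # matches cor.test exactly
  set.seed(52)
  a <- rnorm(30); b <- a + rnorm(30)
  ct <- cor.test(a, b)
  res2 <- correlate_with_severity(a, b)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-12)
})

test_that("p(r, n) is monotone in |r| and in n", {
  rs <- seq(0.05, 0.9, by = 0.05)
  ps <- r_to_p(rs, 61)
  expect_true(all(diff(ps) < 0))
  ns <- c(10, 20, 40, 80, 160)
  ps_n <- sapply(ns, function(n) r_to_p(0.3, n))
  expect_true(all(diff(ps_n) < 0))
})

test_that("significance screen flags |r| >= threshold and counts per slab", {
  set.seed(61)
  idx <- feature_universe("sMRI")[1:500, ]
  n <- 61
  X <- matrix(rnorm(n * 500), n, 500)
  sev <- sample(1:24, n, replace = TRUE)
  # plant a strong severity association in feature 10
  X[, 10] <- 0.8 * scale(sev)[, 1] + 0.6 * rnorm(n)
  sc <- significance_screen(X, idx, sev, threshold_r = 0.32)
  expect_true(sc$significant[10])
  expect_equal(sc$significant, abs(sc$r) >= 0.32)
  cnt <- attr(sc, "counts")
  expect_equal(sum(cnt$per_slab), sum(sc$significant))
  # threshold 1 admits nothing
  sc1 <- significance_screen(X, idx, sev, threshold_r = 1)
  expect_equal(sum(sc1$significant), 0L)
})

test_that("screen type-I rate is near nominal under the null", {
  # scaled-down calibration check (the full-size one runs in the
  # acceptance suite): 2000 independent null features at n = 61
  set.seed(62)
  n <- 61; p <- 2000
  X <- matrix(rnorm(n * p), n, p)
  idx <- feature_universe("fMRI")[1:p, ]
  sev <- rnorm(n)
  sc <- significance_screen(X, idx, sev, threshold_r = 0.32)
  rate <- mean(sc$significant)
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.025)
})

test_that("a planted r = 0.7 feature is flagged reliably", {
  set.seed(63)
  hits <- 0L
  for (rep in 1:50) {
    sev <- rnorm(61)
    x <- 0.7 * sev + sqrt(1 - 0.49) * rnorm(61)
    hits <- hits + (abs(cor(x, sev)) >= 0.32)
  }
  expect_gte(hits, 49L)   # > 99% power at true r = 0.7, n = 61
})

test_that("area frequency counts significant endpoints", {
  scr <- data.frame(i = c(1, 1, 5), j = c(2, 3, 9),
                    significant = c(TRUE, TRUE, FALSE))
  rk <- area_frequency_ranking(scr)
  expect_equal(rk$count[rk$area == 1], 2L)
  expect_equal(rk$count[rk$area == 2], 1L)
  expect_equal(rk$count[rk$area == 3], 1L)
  expect_equal(rk$count[rk$area == 5], 0L)
  expect_equal(rk$area[1], 1L)   # highest count first
  # empty set: all zero
  rk0 <- area_frequency_ranking(scr[scr$i > 99, ])
  expect_true(all(rk0$count == 0L))
  expect_equal(rk0$area, 1:68)   # ties broken by atlas order
})

test_that("area frequencies match a brute-force tally on random pairs", {
  set.seed(64)
  pairs <- t(replicate(50, sort(sample(68, 2))))
  scr <- data.frame(i = pairs[, 1], j = pairs[, 2], significant = TRUE)
  rk <- area_frequency_ranking(scr)
  tally <- integer(68)
  for (r in seq_len(nrow(scr))) {
    tally[scr$i[r]] <- tally[scr$i[r]] + 1L
    tally[scr$j[r]] <- tally[scr$j[r]] + 1L
  }
  expect_equal(rk$count[order(rk$area)], tally)
})

test_that("area ranking is equivariant under region relabelling", {
  set.seed(65)
  pairs <- t(replicate(40, sort(sample(68, 2))))
  scr <- data.frame(i = pairs[, 1], j = pairs[, 2], significant = TRUE)
  perm <- sample(68)
  scr2 <- data.frame(i = pmin(perm[scr$i], perm[scr$j]),
                     j = pmax(perm[scr$i], perm[scr$j]),
                     significant = TRUE)
  c1 <- area_frequency_ranking(scr)
  c2 <- area_frequency_ranking(scr2)
  counts1 <- c1$count[order(c1$area)]
  counts2 <- c2$count[order(c2$area)]
  expect_equal(counts2[perm], counts1)
})

test_that("subgroup-moment reconstruction reproduces the reference age test", {
  ref <- reference_cohort_summaries()$demographics
  res <- demographic_tests_from_moments(ref)
  expect_equal(round(res$age_t$statistic, 2), 0.95)
  expect_equal(res$age_t$p, 0.343, tolerance = 0.01)
  # chi-squared from the same table matches the direct formula
  tab <- xtabs(n ~ sex + label, data = ref)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$sex_chi2$statistic, sum((tab - e)^2 / e),
               tolerance = 1e-12)
})

test_that("moment overload agrees with raw-data tests to high precision", {
  set.seed(66)
  man <- data.frame(
    label = rep(c("ASD", "TD"), c(40, 60)),
    sex = sample(c("M", "F"), 100, replace = TRUE),
    age = rnorm(100, 13, 3),
    ados_total = NA_integer_, ados_sa = NA_integer_,
    ados_rrb = NA_integer_)
  raw <- cohort_demographic_tests(man)
  sums <- do.call(rbind, lapply(split(man, list(man$label, man$sex)),
    function(g) data.frame(label = g$label[1], sex = g$sex[1],
                           n = nrow(g), age_mean = mean(g$age),
                           age_sd = sd(g$age))))
  mom <- demographic_tests_from_moments(sums)
  expect_equal(abs(mom$age_t$statistic), abs(raw$age_t$statistic),
               tolerance = 1e-10)
  expect_equal(mom$age_t$p, raw$age_t$p, tolerance = 1e-10)
  expect_equal(mom$sex_chi2$statistic, raw$sex_chi2$statistic,
               tolerance = 1e-10)
})

test_that("identical group age distributions give t = 0", {
  man <- data.frame(
    label = rep(c("ASD", "TD"), each = 10),
    sex = rep(c("M", "F"), 10),
    age = rep(c(10, 11, 12, 13, 14), 4),
    ados_total = NA_integer_, ados_sa = NA_integer_,
    ados_rrb = NA_integer_)
  res <- cohort_demographic_tests(man)
  expect_equal(res$age_t$statistic, 0, tolerance = 1e-12)
})
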