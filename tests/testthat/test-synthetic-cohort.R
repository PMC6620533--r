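test_that("cohort counts, ADOS availability and missing fMRI follow the config", {
  cfg <- generator_config(n_asd = 72, n_td = 113, n_timepoints = 10,
                          n_ados = 61, n_missing_fmri = 7, seed = 3)
  coh <- generate_cohort(cfg)
  man <- coh$manifest
  expect_equal(nrow(man), 185L)
  expect_equal(sum(man$label == "ASD"), 72L)
  expect_equal(sum(man$label == "TD"), 113L)
  expect_equal(sum(!is.na(man$ados_total)), 61L)
  expect_true(all(!is.na(man$ados_total) == (man$label == "ASD" &
                                             !is.na(man$ados_total))))
  expect_equal(sum(!man$has_fmri), 7L)
  expect_equal(length(coh$timecourses), 178L)
  expect_true(all(man$ados_total >= 1 & man$ados_total <= 24,
                  na.rm = TRUE))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_asd = 4, n_td = 4, n_timepoints = 12,
                          n_ados = 3, n_missing_fmri = 0, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(a$timecourses, b$timecourses)
  expect_identical(generate_morphometry(cfg, "ASD", seed = 9),
                   generate_morphometry(cfg, "ASD", seed = 9))
  expect_identical(generate_timecourses(cfg, "TD", seed = 9),
                   generate_timecourses(cfg, "TD", seed = 9))
})

test_that("written cohorts are io_formats-conformant and reproducible", {
  cfg <- generator_config(n_asd = 3, n_td = 3, n_timepoints = 8,
                          n_ados = 2, n_missing_fmri = 1, seed = 8)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  coh <- generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  # byte-identical regeneration
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # round trip through the readers
  man <- read_cohort_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 6L)
  id <- man$subject_id[1]
  feats <- read_region_features(file.path(d1, "smri", paste0(id, ".csv")))
  expect_equal(feats, coh$morphometry[[id]], tolerance = 1e-10)
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$planted_smri$region, cfg$planted_smri$region)
  expect_equal(gt$planted_edges$delta, cfg$planted_edges$delta)
})

test_that("zero planted effects leave the classes indistinguishable", {
  cfg <- generator_config(n_asd = 40, n_td = 40, n_timepoints = 10,
                          n_ados = 10, n_missing_fmri = 0,
                          planted_smri = NULL, planted_edges = NULL,
                          seed = 12)
  coh <- generate_cohort(cfg)
  man <- coh$manifest
  asd <- names(coh$morphometry)[man$label == "ASD"]
  td <- names(coh$morphometry)[man$label == "TD"]
  # a handful of (region, feature) cells: two-sample t never extreme
  set.seed(13)
  ps <- replicate(12, {
    r <- sample(68, 1); f <- sample(8, 1)
    t.test(sapply(coh$morphometry[asd], function(m) m[r, f]),
           sapply(coh$morphometry[td], function(m) m[r, f]))$p.value
  })
  expect_gt(min(ps), 0.001)
})

test_that("planted morphometric shifts appear at the planted cells only", {
  cfg <- generator_config(n_asd = 150, n_td = 150, n_timepoints = 10,
                          n_ados = 10, n_missing_fmri = 0, seed = 14)
  coh <- generate_cohort(cfg)
  man <- coh$manifest
  asd <- names(coh$morphometry)[man$label == "ASD"]
  td <- names(coh$morphometry)[man$label == "TD"]
  sds <- c(A = 250, V = 500, T_mean = 0.15, T_sd = 0.05, MCI = 0.012,
           K = 0.015, ICI = 0.08, FI = 0.2)
  ps <- cfg$planted_smri
  for (e in seq_len(nrow(ps))) {
    gap <- mean(sapply(coh$morphometry[asd],
                       function(m) m[ps$region[e], ps$f[e]])) -
           mean(sapply(coh$morphometry[td],
                       function(m) m[ps$region[e], ps$f[e]]))
    expect_equal(gap / sds[ps$f[e]], 1.5, tolerance = 0.35,
                 ignore_attr = TRUE)
  }
  # an unplanted cell shows no shift beyond sampling noise
  gap0 <- mean(sapply(coh$morphometry[asd], function(m) m[2, 3])) -
          mean(sapply(coh$morphometry[td], function(m) m[2, 3]))
  expect_lt(abs(gap0 / sds[3]), 0.5)
})

test_that("planted edges shift the empirical connectivity by the delta", {
  cfg <- generator_config(n_asd = 50, n_td = 50, n_timepoints = 180,
                          n_ados = 10, n_missing_fmri = 0, seed = 15)
  coh <- generate_cohort(cfg)
  man <- coh$manifest
  mean_edge <- function(ids, i, j) {
    mean(sapply(coh$timecourses[ids],
                function(tc) cor(tc[i, ], tc[j, ])))
  }
  asd <- man$subject_id[man$label == "ASD"]
  td <- man$subject_id[man$label == "TD"]
  pe <- cfg$planted_edges
  for (e in seq_len(nrow(pe))) {
    diff <- mean_edge(asd, pe$i[e], pe$j[e]) -
            mean_edge(td, pe$i[e], pe$j[e])
    expect_equal(diff, pe$delta[e], tolerance = 0.1)
  }
})

test_that("empirical correlations converge to the target for long series", {
  cfg <- generator_config(n_asd = 2, n_td = 2, n_timepoints = 5000,
                          n_ados = 2, n_missing_fmri = 0, seed = 16)
  structure_target <- neurofuse:::.cohort_structure(cfg)
  tc <- generate_timecourses(cfg, "TD", seed = 17)
  emp <- cor(t(tc))
  expect_lt(max(abs(emp - structure_target$R_td)), 0.08)
})

test_that("over-strong planted edges are rejected as non-positive-definite", {
  bad <- data.frame(i = c(1, 1, 2, 3, 4), j = c(2, 3, 3, 4, 5),
                    delta = 0.9)
  expect_error(
    generator_config(planted_edges = bad, seed = 1),
    "positive-definite|outside")
})

test_that("severity is monotone in a single planted feature without noise", {
  cfg <- generator_config(seed = 2)
  zs <- seq(-2, 2, by = 0.25)
  sev <- sapply(zs, function(z) generate_severity(cfg, z, 1, noise = 0))
  expect_true(all(diff(sev) >= 0))
  expect_true(all(sev >= 1 & sev <= 24))
})

test_that("the designed severity coupling is recovered by the screen", {
  # single strong severity-coupled delta feature; modest cohort
  cfg <- generator_config(n_asd = 72, n_td = 30, n_timepoints = 10,
                          n_ados = 61, n_missing_fmri = 0,
                          planted_edges = NULL, severity_rho = 0.6,
                          seed = 18)
  coh <- generate_cohort(cfg)
  scr <- ados_screen_cohort(coh, threshold_r = 0.32)
  sv <- cfg$severity_smri
  hit <- mapply(function(i, j, f) {
    any(scr$smri$screen$significant &
          scr$smri$screen$i == i & scr$smri$screen$j == j &
          scr$smri$screen$f == f)
  }, sv$i, sv$j, sv$f)
  # with rho = 0.6 split over 5 elements each feature's marginal
  # correlation is rho/sqrt(5) ~ 0.27; at least some should clear 0.32
  expect_gte(sum(hit), 1)
})

test_that("subject-level offsets do not leak into delta features", {
  cfg <- generator_config(n_asd = 2, n_td = 2, n_timepoints = 10,
                          n_ados = 2, offset_sd = 50, seed = 19)
  cfg0 <- generator_config(n_asd = 2, n_td = 2, n_timepoints = 10,
                           n_ados = 2, offset_sd = 0, seed = 19)
  m_big <- generate_morphometry(cfg, "TD", seed = 21)
  m_none <- generate_morphometry(cfg0, "TD", seed = 21)
  # raw features differ wildly, the delta tensors are identical
  expect_gt(max(abs(m_big - m_none)), 1)
  expect_equal(build_delta_tensor(m_big), build_delta_tensor(m_none),
               tolerance = 1e-8)
})
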