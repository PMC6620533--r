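# Shared fixture builders. Everything is generated in code at test
# time; nothing binary is stored in the repository.

atlas <- dk_atlas()

# deterministic 68 x 8 region feature table
fixture_feature_table <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(68 * 8, mean = rep(c(2500, 6000, 2.5, 0.55, 0.13,
                                         0.05, 0.5, 1.0), each = 68),
                    sd = rep(c(250, 500, 0.15, 0.05, 0.012, 0.015,
                               0.08, 0.2), each = 68)),
              nrow = 68, ncol = 8,
              dimnames = list(atlas$name, morphometric_features()))
  m
}

# write a feature table to CSV in a given row order
write_feature_csv <- function(tab, path, order = seq_len(68)) {
  df <- data.frame(region = rownames(tab)[order], tab[order, ],
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

fixture_timecourses <- function(seed = 1, T = 40) {
  set.seed(seed)
  matrix(rnorm(68 * T), nrow = 68,
         dimnames = list(atlas$name, NULL))
}

write_timecourse_csv <- function(tc, path) {
  df <- data.frame(region = rownames(tc), tc, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_manifest_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

minimal_manifest_df <- function() {
  data.frame(
    subject_id = c("A1", "A2", "T1", "T2"),
    label = c("ASD", "ASD", "TD", "TD"),
    sex = c("M", "F", "M", "F"),
    age = c(12.5, 13.1, 11.9, 14.0),
    ados_total = c(12, 8, NA, NA),
    ados_sa = c(9, 6, NA, NA),
    ados_rrb = c(3, 2, NA, NA),
    has_smri = 1, has_fmri = 1,
    stringsAsFactors = FALSE
  )
}

# small but classification-viable synthetic cohort
small_cohort <- function(seed = 1, n_asd = 12, n_td = 12, T = 40,
                         n_missing_fmri = 0, ...) {
  cfg <- generator_config(n_asd = n_asd, n_td = n_td, n_timepoints = T,
                          n_ados = min(10, n_asd),
                          n_missing_fmri = n_missing_fmri,
                          seed = seed, ...)
  generate_cohort(cfg)
}

# single-hyperparameter grid for fast classifier tests
tiny_grid <- function() data.frame(num_trees = 100L, max_depth = 0L)
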