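#' Synthetic cohort generator configuration
#'
#' Describes a synthetic multimodal cohort with the statistical
#' structure the pipeline assumes: region-level morphometric features
#' with a per-subject global offset (a head-size-like confound that
#' the delta tensor cancels), region time courses drawn from a
#' multivariate Gaussian whose correlation matrix carries
#' class-specific planted edges, a partially observed ADOS-like
#' severity score correlated with designated planted features, and
#' demographics mirroring a 72 ASD / 113 TD cohort.
#'
#' Default planted effects: five (region, feature-slab) morphometric
#' elements shifted by 1.5 within-region SD in the ASD class, and five
#' connectivity edges whose correlation differs by |0.4| between
#' classes (a mix of hyper- and hypo-connectivity). Severity couples
#' to one delta feature per planted morphometric element and to the
#' planted edges, with a designed feature-severity correlation of 0.6.
#'
#' @param n_asd,n_td Subject counts per class (defaults 72 / 113).
#' @param n_timepoints Time points per BOLD time course (default 180,
#'   i.e. ~6 min at TR = 2 s).
#' @param n_ados Number of ASD subjects carrying an ADOS total score
#'   (default 61; TD subjects carry none).
#' @param n_missing_fmri Subjects whose fMRI is marked unusable and
#'   excluded from connectivity analysis and fusion (default 7).
#' @param planted_smri Data frame `region, f, shift_sd`: ASD mean
#'   shift, in units of the region/feature SD.
#' @param planted_edges Data frame `i, j, delta`: additive change of
#'   the ASD correlation on edge (i, j). The resulting target matrix
#'   must stay positive definite (checked; smallest eigenvalue >
#'   1e-6).
#' @param severity_smri Data frame `i, j, f, weight`: delta features
#'   driving severity.
#' @param severity_edges Data frame `i, j, weight`: connectivity edges
#'   driving severity.
#' @param severity_rho Designed correlation between the (standardized)
#'   weighted planted signal and the latent severity (default 0.6).
#' @param noise_sd Multiplier on the within-region feature SDs
#'   (default 1).
#' @param offset_sd Scale of the per-subject global offset, in feature
#'   SD units (default 1).
#' @param seed Integer seed; everything the generator draws is a
#'   deterministic function of it.
#' @param structure_seed Seed for the fixed "anatomy" (region baseline
#'   means and the base connectivity structure), kept separate from
#'   `seed` so different cohorts share one underlying population.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_asd = 72L, n_td = 113L,
                             n_timepoints = 180L, n_ados = 61L,
                             n_missing_fmri = 7L,
                             planted_smri = default_planted_smri(),
                             planted_edges = default_planted_edges(),
                             severity_smri = NULL,
                             severity_edges = NULL,
                             severity_rho = 0.6,
                             noise_sd = 1, offset_sd = 1,
                             seed = 1L, structure_seed = 1004L) {
  if (n_asd < 2L || n_td < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  if (n_timepoints < 3L) stop("need at least 3 time points", call. = FALSE)
  n_ados <- min(n_ados, n_asd)
  if (!is.null(planted_smri) && nrow(planted_smri)) {
    stopifnot(all(planted_smri$region %in% 1:68),
              all(planted_smri$f %in% 1:8))
  }
  if (is.null(severity_smri) && !is.null(planted_smri) &&
      nrow(planted_smri)) {
    # couple severity to one delta feature per planted element,
    # pairing each planted region with a fixed unplanted partner
    partner <- (planted_smri$region %% 68L) + 1L
    clash <- partner %in% planted_smri$region
    partner[clash] <- (partner[clash] %% 68L) + 1L
    severity_smri <- data.frame(
      i = pmin(planted_smri$region, partner),
      j = pmax(planted_smri$region, partner),
      f = planted_smri$f, weight = 1)
  }
  if (is.null(severity_edges) && !is.null(planted_edges) &&
      nrow(planted_edges)) {
    severity_edges <- data.frame(i = planted_edges$i,
                                 j = planted_edges$j, weight = 1)
  }
  cfg <- list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
              n_timepoints = as.integer(n_timepoints),
              n_ados = as.integer(n_ados),
              n_missing_fmri = as.integer(n_missing_fmri),
              planted_smri = planted_smri,
              planted_edges = planted_edges,
              severity_smri = severity_smri,
              severity_edges = severity_edges,
              severity_rho = severity_rho,
              noise_sd = noise_sd, offset_sd = offset_sd,
              seed = as.integer(seed),
              structure_seed = as.integer(structure_seed))
  class(cfg) <- "generator_config"
  # fail early if the planted edges break positive definiteness
  invisible(.cohort_structure(cfg))
  cfg
}

#' Default planted morphometric effects
#'
#' Five (region, feature slab) elements shifted by 1.5 SD in ASD,
#' spread over both hemispheres and five different feature slabs.
#'
#' @return Data frame `region, f, shift_sd`.
#' @export
default_planted_smri <- function() {
  data.frame(region = c(7L, 20L, 31L, 45L, 60L),
             f = c(1L, 2L, 4L, 8L, 5L),
             shift_sd = 1.5)
}

#' Default planted connectivity effects
#'
#' Five edges whose ASD correlation differs by |0.4| from the TD
#' correlation (three hyper-connected, two hypo-connected).
#'
#' @return Data frame `i, j, delta`.
#' @export
default_planted_edges <- function() {
  data.frame(i = c(3L, 12L, 25L, 40L, 55L),
             j = c(18L, 30L, 47L, 62L, 66L),
             delta = c(0.4, 0.4, -0.4, 0.4, -0.4))
}

# Fixed population structure: region baseline means, per-feature SDs,
# and the TD / ASD target correlation matrices.
.cohort_structure <- function(cfg) {
  rng <- .local_rng(cfg$structure_seed)
  u <- function(n, lo, hi) lo + (hi - lo) * rng(n)
  feature_sds <- c(A = 250, V = 500, T_mean = 0.15, T_sd = 0.05,
                   MCI = 0.012, K = 0.015, ICI = 0.08, FI = 0.2)
  region_means <- cbind(
    A = u(68, 1500, 3500), V = u(68, 3000, 9000),
    T_mean = u(68, 2.0, 3.2), T_sd = u(68, 0.4, 0.7),
    MCI = u(68, 0.10, 0.16), K = u(68, 0.0, 0.1),
    ICI = u(68, 0.2, 0.8), FI = u(68, 0.5, 1.5))

  # base functional connectivity: low-rank factor structure + noise,
  # rescaled to a correlation matrix
  B <- matrix(stats::qnorm(rng(68 * 3)), 68, 3) * 0.3
  S <- B %*% t(B) + diag(1, 68)
  d <- sqrt(diag(S))
  R0 <- S / outer(d, d)
  R_asd <- R0
  pe <- cfg$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    for (e in seq_len(nrow(pe))) {
      v <- R0[pe$i[e], pe$j[e]] + pe$delta[e]
      if (abs(v) >= 1) {
        stop("planted edge (", pe$i[e], ",", pe$j[e],
             ") pushes the correlation outside (-1, 1); ",
             "use a smaller delta", call. = FALSE)
      }
      R_asd[pe$i[e], pe$j[e]] <- v
      R_asd[pe$j[e], pe$i[e]] <- v
    }
    ev <- min(eigen(R_asd, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-6) {
      stop("planted edge deltas make the ASD correlation matrix ",
           "non-positive-definite (min eigenvalue ", signif(ev, 3),
           "); use smaller deltas", call. = FALSE)
    }
  }
  list(region_means = region_means, feature_sds = feature_sds,
       R_td = R0, R_asd = R_asd,
       chol_td = chol(R0), chol_asd = chol(R_asd))
}

# Draw one subject's 68 x 8 morphometry. Returns the matrix plus the
# standardized region residuals (confound-free) used for severity.
.draw_morphometry <- function(cfg, structure, class_label) {
  sds <- structure$feature_sds * cfg$noise_sd
  resid <- matrix(rnorm(68 * 8), 68, 8)       # standardized residuals
  offsets <- rnorm(8, sd = cfg$offset_sd)     # head-size-like confound
  values <- structure$region_means +
    sweep(resid, 2L, sds, "*") +
    matrix(rep(offsets * structure$feature_sds, each = 68), 68, 8)
  if (class_label == "ASD" && !is.null(cfg$planted_smri) &&
      nrow(cfg$planted_smri)) {
    ps <- cfg$planted_smri
    values[cbind(ps$region, ps$f)] <-
      values[cbind(ps$region, ps$f)] + ps$shift_sd * sds[ps$f]
    resid[cbind(ps$region, ps$f)] <-
      resid[cbind(ps$region, ps$f)] + ps$shift_sd
  }
  dimnames(values) <- list(dk_atlas()$name, morphometric_features())
  list(values = values, resid = resid)
}

# Draw one subject's 68 x T time-course matrix from the class target
# correlation via its Cholesky factor.
.draw_timecourses <- function(cfg, structure, class_label) {
  ch <- if (class_label == "ASD") structure$chol_asd else structure$chol_td
  Z <- matrix(rnorm(cfg$n_timepoints * 68L), cfg$n_timepoints, 68L)
  tc <- t(Z %*% ch)
  rownames(tc) <- dk_atlas()$name
  tc
}

#' Generate one subject's morphometric feature table
#'
#' Region baseline values are drawn from region-specific Gaussians
#' shared by both classes; ASD subjects additionally receive the
#' planted mean shifts; every subject gets a global per-feature offset
#' (a head-size-like confound) that the delta tensor cancels exactly.
#'
#' @param config A `generator_config`.
#' @param class_label `"ASD"` or `"TD"`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A 68 x 8 matrix in canonical atlas/feature order.
#' @export
generate_morphometry <- function(config, class_label = "TD",
                                 seed = config$seed) {
  structure <- .cohort_structure(config)
  .with_seed(seed, .draw_morphometry(config, structure, class_label))$values
}

#' Generate one subject's region time courses
#'
#' Draws T samples from a zero-mean multivariate Gaussian whose
#' correlation matrix is the shared low-rank base structure, plus the
#' class-specific planted edge deltas for ASD subjects.
#'
#' @inheritParams generate_morphometry
#' @return A 68 x T matrix.
#' @export
generate_timecourses <- function(config, class_label = "TD",
                                 seed = config$seed) {
  structure <- .cohort_structure(config)
  .with_seed(seed, .draw_timecourses(config, structure, class_label))
}

#' Generate an ADOS-like severity score
#'
#' Maps a subject's standardized planted-effect magnitudes to an
#' integer severity in \[1, 24\]: a weighted combination of the
#' effects, mixed with Gaussian noise so the designed feature-severity
#' correlation equals `config$severity_rho`, then affinely mapped,
#' rounded and clipped.
#'
#' @param config A `generator_config`.
#' @param z_effects Numeric vector of standardized planted-effect
#'   deviations for this subject.
#' @param weights Weights matching `z_effects` (default all 1).
#' @param noise Standard normal noise draw (supply 0 for a noise-free
#'   score).
#' @return Integer severity in \[1, 24\].
#' @export
generate_severity <- function(config, z_effects,
                              weights = rep(1, length(z_effects)),
                              noise = rnorm(1)) {
  rho <- config$severity_rho
  signal <- if (length(z_effects)) {
    sum(weights * z_effects) / sqrt(sum(weights^2))
  } else 0
  z <- rho * signal + sqrt(1 - rho^2) * noise
  as.integer(pmin(24, pmax(1, round(11.5 + 5 * z))))
}

# run expr with a temporary RNG state seeded at `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a full synthetic cohort
#'
#' Draws the whole cohort — manifest with demographics, per-subject
#' morphometry and time courses, severity scores for the scored ASD
#' subset — and optionally writes it to disk in the package's file
#' formats together with a ground-truth sidecar naming the planted
#' elements. Deterministic given `config$seed`.
#'
#' Demographics mirror the reference cohort shape: sex assigned in the
#' subgroup proportions 33M/39F (ASD) and 49M/64F (TD), ages drawn
#' from the corresponding subgroup Gaussians (means 13.07/13.53/
#' 13.04/12.81 years, SDs 2.75/2.58/2.68/3.17).
#'
#' @param config A `generator_config`.
#' @param out_dir If non-`NULL`, write `manifest.csv`, `smri/<id>.csv`,
#'   `fmri/<id>.csv` and `ground_truth.json` under this directory.
#' @return List of class `synthetic_cohort`: `manifest` (a
#'   `cohort_manifest`), `morphometry` (named list of 68 x 8 matrices),
#'   `timecourses` (named list of 68 x T matrices; absent for
#'   missing-fMRI subjects), `ground_truth`, and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  structure <- .cohort_structure(config)
  atlas <- dk_atlas()
  n <- config$n_asd + config$n_td
  out <- .with_seed(config$seed, {
    ids <- sprintf("S%03d", seq_len(n))
    label <- c(rep("ASD", config$n_asd), rep("TD", config$n_td))

    # demographics in the reference subgroup proportions
    sex <- character(n)
    asd_m <- round(config$n_asd * 33 / 72)
    td_m <- round(config$n_td * 49 / 113)
    sex[label == "ASD"] <- sample(rep(c("M", "F"),
                                      c(asd_m, config$n_asd - asd_m)))
    sex[label == "TD"] <- sample(rep(c("M", "F"),
                                     c(td_m, config$n_td - td_m)))
    age_mean <- c("ASD.M" = 13.07, "ASD.F" = 13.53,
                  "TD.M" = 13.04, "TD.F" = 12.81)
    age_sd <- c("ASD.M" = 2.75, "ASD.F" = 2.58,
                "TD.M" = 2.68, "TD.F" = 3.17)
    grp <- paste(label, sex, sep = ".")
    age <- round(pmax(5, rnorm(n, age_mean[grp], age_sd[grp])), 2)

    missing_fmri <- if (config$n_missing_fmri > 0L) {
      sort(sample(n, min(config$n_missing_fmri, n)))
    } else integer(0)
    scored <- sort(sample(which(label == "ASD"), config$n_ados))

    morph <- vector("list", n); names(morph) <- ids
    tcs <- vector("list", n); names(tcs) <- ids
    ados <- rep(NA_integer_, n)
    sev_s <- config$severity_smri
    sev_e <- config$severity_edges
    for (s in seq_len(n)) {
      mm <- .draw_morphometry(config, structure, label[s])
      morph[[s]] <- mm$values
      has_fmri <- !(s %in% missing_fmri)
      if (has_fmri) tcs[[s]] <- .draw_timecourses(config, structure, label[s])
      if (s %in% scored) {
        z <- numeric(0); w <- numeric(0)
        if (!is.null(sev_s) && nrow(sev_s)) {
          # standardized delta features, confound-free by construction
          z <- c(z, (mm$resid[cbind(sev_s$i, sev_s$f)] -
                       mm$resid[cbind(sev_s$j, sev_s$f)]) / sqrt(2))
          w <- c(w, sev_s$weight)
        }
        if (!is.null(sev_e) && nrow(sev_e) && has_fmri) {
          rho_t <- structure$R_asd[cbind(sev_e$i, sev_e$j)]
          rho_e <- vapply(seq_len(nrow(sev_e)), function(e) {
            cor(tcs[[s]][sev_e$i[e], ], tcs[[s]][sev_e$j[e], ])
          }, numeric(1))
          se <- (1 - rho_t^2) / sqrt(config$n_timepoints - 1)
          z <- c(z, (rho_e - rho_t) / se)
          w <- c(w, sev_e$weight)
        }
        ados[s] <- generate_severity(config, z, w, rnorm(1))
      }
    }
    # crude sub-score split of the total, for descriptive statistics
    sa <- ifelse(is.na(ados), NA_integer_,
                 pmin(19L, pmax(0L, as.integer(round(ados * 0.75)))))
    rrb <- ifelse(is.na(ados), NA_integer_,
                  pmin(6L, pmax(0L, ados - sa)))
    manifest <- data.frame(
      subject_id = ids, label = factor(label, levels = c("TD", "ASD")),
      sex = sex, age = age, ados_total = ados, ados_sa = sa,
      ados_rrb = rrb, has_smri = TRUE,
      has_fmri = !seq_len(n) %in% missing_fmri,
      stringsAsFactors = FALSE)
    class(manifest) <- c("cohort_manifest", "data.frame")
    attr(manifest, "atlas") <- atlas
    list(manifest = manifest, morphometry = morph,
         timecourses = tcs[!vapply(tcs, is.null, logical(1))])
  })
  out$ground_truth <- list(
    planted_smri = config$planted_smri,
    planted_edges = config$planted_edges,
    severity_smri = config$severity_smri,
    severity_edges = config$severity_edges,
    severity_rho = config$severity_rho)
  out$config <- config
  class(out) <- "synthetic_cohort"
  if (!is.null(out_dir)) .write_cohort(out, out_dir, atlas)
  out
}

.write_cohort <- function(cohort, out_dir, atlas) {
  dir.create(file.path(out_dir, "smri"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "fmri"), recursive = TRUE,
             showWarnings = FALSE)
  man <- cohort$manifest
  man$has_smri <- as.integer(man$has_smri)
  man$has_fmri <- as.integer(man$has_fmri)
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  for (id in names(cohort$morphometry)) {
    tab <- data.frame(region = atlas$name, cohort$morphometry[[id]],
                      check.names = FALSE)
    write.csv(tab, file.path(out_dir, "smri", paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  for (id in names(cohort$timecourses)) {
    tab <- data.frame(region = atlas$name, cohort$timecourses[[id]],
                      check.names = FALSE)
    write.csv(tab, file.path(out_dir, "fmri", paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
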