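#' Assemble per-modality cohort feature matrices from raw data
#'
#' Builds delta tensors from every subject's morphometry and
#' connectivity matrices from every subject's time courses, then
#' flattens them into the two subjects x features matrices used by the
#' classification stages.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or any
#'   list with `manifest`, `morphometry` (named list of 68 x 8
#'   matrices) and `timecourses` (named list of 68 x T matrices).
#' @return List with `smri` and `fmri` entries (each `X`, `index`,
#'   `subject_ids`, `labels`) and `manifest`.
#' @export
prepare_feature_matrices <- function(cohort) {
  man <- cohort$manifest
  smri_ids <- intersect(man$subject_id[man$has_smri],
                        names(cohort$morphometry))
  fmri_ids <- intersect(man$subject_id[man$has_fmri],
                        names(cohort$timecourses))
  smri <- NULL
  if (length(smri_ids)) {
    deltas <- lapply(cohort$morphometry[smri_ids], build_delta_tensor)
    fm <- cohort_feature_matrix(deltas, "sMRI")
    smri <- list(X = fm$X, index = fm$index, subject_ids = smri_ids,
                 labels = man$label[match(smri_ids, man$subject_id)])
  }
  fmri <- NULL
  if (length(fmri_ids)) {
    conns <- lapply(cohort$timecourses[fmri_ids], function(tc) {
      suppressWarnings(connectivity_matrix(tc))
    })
    fm <- cohort_feature_matrix(conns, "fMRI")
    fmri <- list(X = fm$X, index = fm$index, subject_ids = fmri_ids,
                 labels = man$label[match(fmri_ids, man$subject_id)])
  }
  list(smri = smri, fmri = fmri, manifest = man)
}

#' Run the full two-stage diagnosis pipeline
#'
#' Executes the pipeline end to end on a cohort: (1) one local KNN
#' classifier per pairwise feature, giving cross-validated accuracies
#' and out-of-fold autism probabilities; (2) accuracy-ranked prefix
#' scan with a grid-searched random forest per modality; (3) fusion of
#' the optimal prefixes into a global classifier on the subjects that
#' carry both modalities; plus personalized per-area probability maps.
#'
#' `mode = "pooled"` ranks features on the full cohort before the
#' global cross-validation — the classical protocol of this pipeline
#' family, simple but optimistic, since the ranking has seen the test
#' folds. `mode = "nested"` additionally reports, for the chosen
#' prefix lengths, metrics in which the local ranking is recomputed
#' inside every outer training fold (no leakage).
#'
#' @param cohort See [prepare_feature_matrices()].
#' @param k Local KNN neighbour count (default 7).
#' @param folds Outer fold count (default 4).
#' @param max_prefix Longest ranked prefix scanned (default 100).
#' @param grid Random-forest hyperparameter grid.
#' @param seed Integer seed for folds, tie-breaks and forests.
#' @param mode `"pooled"` or `"nested"`.
#' @param compute_maps Build personalized maps (default TRUE).
#' @param benchmark Also run the four-classifier comparison on the
#'   fused features (default FALSE).
#' @return List of class `neurofuse_result` with `local` (per-modality
#'   grids and rankings), `scan` (per-modality prefix curves),
#'   `fusion`, `nested` (when requested), `maps`, `benchmark`,
#'   `subjects` (per-subject fused out-of-fold predictions) and
#'   `metrics` summary.
#' @export
run_autism_cad <- function(cohort, k = 7L, folds = 4L, max_prefix = 100L,
                           grid = default_rf_grid(), seed = 1L,
                           mode = c("pooled", "nested"),
                           compute_maps = TRUE, benchmark = FALSE) {
  mode <- match.arg(mode)
  fm <- prepare_feature_matrices(cohort)
  if (is.null(fm$smri) || is.null(fm$fmri)) {
    stop("pipeline needs both modalities; run the stages directly for ",
         "a single-modality analysis", call. = FALSE)
  }

  local <- list(); scan <- list()
  for (mod in c("smri", "fmri")) {
    m <- fm[[mod]]
    grid_res <- evaluate_local_grid(m$X, m$labels, folds = folds, k = k,
                                    seed = seed)
    ranked <- rank_features(grid_res, m$index)
    local[[mod]] <- list(grid = grid_res, ranked = ranked)
  }

  # fusion-eligible subjects: both modalities present
  both <- intersect(fm$smri$subject_ids, fm$fmri$subject_ids)
  s_rows <- match(both, fm$smri$subject_ids)
  f_rows <- match(both, fm$fmri$subject_ids)
  labels_both <- fm$smri$labels[s_rows]
  fold_both <- make_stratified_folds(labels_both, folds, seed = seed)

  for (mod in c("smri", "fmri")) {
    m <- fm[[mod]]
    rows <- if (mod == "smri") s_rows else f_rows
    scan[[mod]] <- incremental_selection(
      local[[mod]]$ranked, m$X[rows, , drop = FALSE], labels_both,
      max_prefix = max_prefix, folds = fold_both, grid = grid,
      seed = seed)
  }

  fusion <- fuse_modalities(
    scan$smri, scan$fmri,
    fm$smri$X[s_rows, , drop = FALSE],
    fm$fmri$X[f_rows, , drop = FALSE],
    labels_both, folds = fold_both, grid = grid, seed = seed)

  nested <- NULL
  if (mode == "nested") {
    nested <- list(
      smri = evaluate_nested_prefix(
        fm$smri$X[s_rows, , drop = FALSE], labels_both, fm$smri$index,
        L = scan$smri$chosen_length, folds = fold_both, k = k,
        grid = grid, seed = seed),
      fmri = evaluate_nested_prefix(
        fm$fmri$X[f_rows, , drop = FALSE], labels_both, fm$fmri$index,
        L = scan$fmri$chosen_length, folds = fold_both, k = k,
        grid = grid, seed = seed))
  }

  maps <- NULL
  if (compute_maps) {
    # maps use each modality's full subject set; missing-modality
    # subjects get a map for the available modality only
    all_ids <- fm$manifest$subject_id
    maps <- vector("list", length(all_ids)); names(maps) <- all_ids
    for (s in seq_along(all_ids)) {
      id <- all_ids[s]
      si <- match(id, fm$smri$subject_ids)
      fi <- match(id, fm$fmri$subject_ids)
      P_S <- if (!is.na(si)) {
        subject_probability_structure(local$smri$grid$prob[si, ],
                                      fm$smri$index)
      }
      P_F <- if (!is.na(fi)) {
        subject_probability_structure(local$fmri$grid$prob[fi, ],
                                      fm$fmri$index)
      }
      if (is.null(P_S) && is.null(P_F)) next
      maps[[s]] <- build_personalized_map(P_F, P_S, id)
    }
    maps <- maps[!vapply(maps, is.null, logical(1))]
  }

  bench <- NULL
  if (benchmark) {
    fused_X <- cbind(
      fm$smri$X[s_rows, fusion$smri_prefix$column, drop = FALSE],
      fm$fmri$X[f_rows, fusion$fmri_prefix$column, drop = FALSE])
    bench <- benchmark_classifiers(fused_X, labels_both,
                                   folds = fold_both, grid = grid,
                                   seed = seed)
  }

  subjects <- data.frame(
    subject_id = both,
    true_label = as.character(labels_both),
    predicted_label = fusion$metrics$predicted,
    autism_probability = fusion$metrics$scores,
    stringsAsFactors = FALSE)

  metrics <- list(
    smri = scan$smri$curve[scan$smri$chosen_length,
                           c("accuracy", "sensitivity", "specificity", "auc")],
    fmri = scan$fmri$curve[scan$fmri$chosen_length,
                           c("accuracy", "sensitivity", "specificity", "auc")],
    fused = fusion$metrics[c("accuracy", "sensitivity", "specificity", "auc")],
    fused_length = fusion$fused_length)

  out <- list(local = local, scan = scan, fusion = fusion,
              nested = nested, maps = maps, benchmark = bench,
              subjects = subjects, metrics = metrics,
              feature_matrices = fm, seed = seed)
  class(out) <- "neurofuse_result"
  out
}

#' Nested (leakage-free) evaluation of a ranked prefix
#'
#' Evaluates a prefix of length `L` while recomputing the local-KNN
#' feature ranking inside every outer training fold, so the feature
#' selection never sees the test subjects. The out-of-fold scores are
#' pooled into the usual four metrics.
#'
#' @param X Subjects x all-features matrix.
#' @param labels Class labels.
#' @param index Feature universe for `X`.
#' @param L Prefix length to evaluate.
#' @param folds Fold count or assignment.
#' @param k Local KNN neighbour count.
#' @param grid,seed As in [evaluate_feature_prefix()].
#' @return A `cv_metrics` list.
#' @export
evaluate_nested_prefix <- function(X, labels, index, L, folds = 4L,
                                   k = 7L, grid = default_rf_grid(),
                                   seed = 1L) {
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(folds) == 1L) {
    folds <- make_stratified_folds(labels, as.integer(folds), seed = seed)
  }
  scores <- numeric(nrow(X))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    inner <- evaluate_local_grid(X[tr, , drop = FALSE], labels[tr],
                                 folds = 4L, k = k, seed = seed + f)
    ranked <- rank_features(inner, index)
    cols <- ranked$column[seq_len(min(L, nrow(ranked)))]
    params <- .grid_search_rf(X[tr, cols, drop = FALSE], labels[tr],
                              grid, seed = seed + 100L * f)
    scores[!tr] <- .fit_score("rf", X[tr, cols, drop = FALSE], labels[tr],
                              X[!tr, cols, drop = FALSE], params, seed + f)
  }
  predicted <- ifelse(scores > 0.5, "ASD", "TD")
  m <- classification_metrics(predicted, labels, scores)
  out <- c(m, list(scores = scores, predicted = predicted, folds = folds,
                   hyperparameters = NULL))
  class(out) <- "cv_metrics"
  out
}

#' Severity correlation screen for a cohort
#'
#' Runs [significance_screen()] for both modalities over the subjects
#' that carry an ADOS total score, and ranks atlas areas by how often
#' they participate in significant features.
#'
#' @param cohort See [prepare_feature_matrices()].
#' @param threshold_r Absolute-correlation threshold (default 0.32,
#'   i.e. p = 0.01 at n = 61).
#' @param bh_fdr Also report BH-adjusted p-values.
#' @return List with `smri`, `fmri` (each `screen`, `areas`), and `n`.
#' @export
ados_screen_cohort <- function(cohort, threshold_r = 0.32,
                               bh_fdr = FALSE) {
  fm <- prepare_feature_matrices(cohort)
  man <- fm$manifest
  scored <- man$subject_id[!is.na(man$ados_total)]
  out <- list()
  for (mod in c("smri", "fmri")) {
    m <- fm[[mod]]
    if (is.null(m)) next
    ids <- intersect(scored, m$subject_ids)
    if (length(ids) < 4L) next
    rows <- match(ids, m$subject_ids)
    sev <- man$ados_total[match(ids, man$subject_id)]
    sc <- significance_screen(m$X[rows, , drop = FALSE], m$index, sev,
                              threshold_r = threshold_r, bh_fdr = bh_fdr)
    out[[mod]] <- list(screen = sc, areas = area_frequency_ranking(sc),
                       n = length(ids))
  }
  out
}

#' Build the per-subject diagnosis results block for a report
#'
#' @param result A `neurofuse_result` from [run_autism_cad()].
#' @return A list suitable for [write_diagnosis_report()].
#' @export
diagnosis_results <- function(result) {
  list(subjects = result$subjects,
       metrics = list(
         smri = as.list(result$metrics$smri),
         fmri = as.list(result$metrics$fmri),
         fused = result$metrics$fused,
         fused_length = result$metrics$fused_length))
}
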