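#' Area under the ROC curve from scores
#'
#' Trapezoidal AUC of the ROC curve for autism-probability scores,
#' computed via the rank (Mann-Whitney) identity, which equals the
#' trapezoidal integral of the empirical ROC with ties handled by the
#' midpoint convention.
#'
#' @param scores Numeric scores (higher = more ASD-like).
#' @param labels Labels; ASD is the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.character(labels) == "ASD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from pooled predictions
#'
#' @param predicted Predicted labels (`"ASD"`/`"TD"`).
#' @param truth True labels; ASD is the positive class.
#' @param scores Autism-probability scores for the AUC.
#' @return Named list: `accuracy`, `sensitivity` (TP/(TP+FN)),
#'   `specificity` (TN/(TN+FP)), `auc`, and the confusion counts.
#' @export
classification_metrics <- function(predicted, truth, scores = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  tp <- sum(predicted == "ASD" & truth == "ASD")
  fn <- sum(predicted == "TD" & truth == "ASD")
  tn <- sum(predicted == "TD" & truth == "TD")
  fp <- sum(predicted == "ASD" & truth == "TD")
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       auc = if (is.null(scores)) NA_real_ else roc_auc(scores, truth),
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' Default random-forest hyperparameter grid
#'
#' Number of trees in \{10, 50, 100, 200\} crossed with maximum tree
#' depth in \{2, 4, 8, unbounded\} (0 encodes unbounded). Trees split
#' on the Gini impurity.
#'
#' @return Data frame with columns `num_trees`, `max_depth`.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(10L, 50L, 100L, 200L),
              max_depth = c(2L, 4L, 8L, 0L))
}

# Fit one classifier family on (Xtr, ytr); return ASD scores for Xte.
# y levels are c("TD", "ASD") throughout.
.fit_score <- function(classifier, Xtr, ytr, Xte, params, seed) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  colnames(Xtr) <- colnames(Xte) <- paste0("x", seq_len(ncol(Xtr)))
  switch(classifier,
    rf = {
      fit <- ranger::ranger(
        x = Xtr, y = ytr,
        num.trees = params$num_trees,
        max.depth = params$max_depth,
        splitrule = "gini",
        probability = TRUE,
        seed = seed,
        num.threads = 1L
      )
      predict(fit, data = Xte, num.threads = 1L)$predictions[, "ASD"]
    },
    svm = {
      # decision values, not Platt probabilities: libsvm's probability
      # calibration uses an internal RNG that R's seed does not control
      fit <- e1071::svm(Xtr, ytr, kernel = "radial")
      pr <- predict(fit, Xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1L]
      if (!startsWith(colnames(attr(pr, "decision.values"))[1L], "ASD")) {
        dv <- -dv
      }
      stats::plogis(dv)
    },
    nb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      predict(fit, Xte, type = "raw")[, "ASD"]
    },
    nnet = {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2L, sd); sg[sg == 0] <- 1
      Ztr <- scale(Xtr, mu, sg); Zte <- scale(Xte, mu, sg)
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      fit <- nnet::nnet(Ztr, as.numeric(ytr == "ASD"), size = 8L,
                        decay = 0.01, maxit = 300L, trace = FALSE)
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      as.numeric(predict(fit, Zte))
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

# Inner grid search for the random forest: pick the (num_trees,
# max_depth) pair with the best inner-CV accuracy (ties -> first in
# grid order, i.e. the simpler model).
.grid_search_rf <- function(Xtr, ytr, grid, inner_folds = 3L, seed = 1L) {
  if (nrow(grid) == 1L) return(grid[1L, ])
  fold <- make_stratified_folds(ytr, n_folds = inner_folds, seed = seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      sc <- .fit_score("rf", Xtr[tr, , drop = FALSE], ytr[tr],
                       Xtr[!tr, , drop = FALSE], grid[g, ], seed + f)
      pred <- ifelse(sc > 0.5, "ASD", "TD")
      correct <- correct + sum(pred == as.character(ytr[!tr]))
    }
    acc[g] <- correct / length(ytr)
  }
  grid[which.max(acc), ]
}

#' Cross-validated evaluation of a feature subset
#'
#' Evaluates a feature table with the pipeline's standard protocol:
#' stratified outer cross-validation (default fourfold); on every
#' outer training split, a grid search over the random-forest
#' hyperparameters (number of trees and maximum depth) by inner
#' threefold cross-validation; out-of-fold autism probabilities pooled
#' across folds for the accuracy, sensitivity (ASD positive),
#' specificity and trapezoidal AUC.
#'
#' @param X Subjects x features matrix (the selected features only).
#' @param labels Class labels (`"ASD"`/`"TD"`).
#' @param folds Fold count (default 4) or explicit fold assignment.
#' @param grid Hyperparameter grid (see [default_rf_grid()]).
#' @param seed Integer seed controlling folds and forest randomness.
#' @param classifier Classifier family: `"rf"` (grid-searched),
#'   `"svm"`, `"nb"` or `"nnet"`.
#' @return List of class `cv_metrics`: the four metrics, confusion
#'   counts, pooled out-of-fold `scores`, `predicted`, `folds`, and
#'   the per-fold chosen hyperparameters.
#' @export
evaluate_feature_prefix <- function(X, labels, folds = 4L,
                                    grid = default_rf_grid(), seed = 1L,
                                    classifier = "rf") {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("empty feature set", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(folds) == 1L) {
    folds <- make_stratified_folds(labels, as.integer(folds), seed = seed)
  }
  scores <- numeric(nrow(X))
  chosen <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(labels[folds == f])) < 2L) {
      stop("degenerate fold ", f, ": contains a single class", call. = FALSE)
    }
    params <- NULL
    if (classifier == "rf") {
      params <- .grid_search_rf(X[tr, , drop = FALSE], labels[tr], grid,
                                seed = seed + 100L * f)
      chosen[[f]] <- params
    }
    scores[!tr] <- .fit_score(classifier, X[tr, , drop = FALSE],
                              labels[tr], X[!tr, , drop = FALSE],
                              params, seed + f)
  }
  predicted <- ifelse(scores > 0.5, "ASD", "TD")
  m <- classification_metrics(predicted, labels, scores)
  out <- c(m, list(scores = scores, predicted = predicted, folds = folds,
                   hyperparameters = chosen))
  class(out) <- "cv_metrics"
  out
}

#' Incremental ranked-prefix feature selection
#'
#' Scans prefixes of the accuracy-ranked feature list, adding one
#' feature at a time and recording the cross-validated accuracy,
#' sensitivity, specificity and AUC of each prefix. The chosen prefix
#' length is the smallest one attaining the maximum accuracy.
#'
#' @param ranked A `ranked_features` data frame from [rank_features()].
#' @param X Subjects x all-features matrix the ranking refers to
#'   (columns in universe order).
#' @param labels Class labels.
#' @param max_prefix Longest prefix scanned (default 100).
#' @param folds,grid,seed Passed to [evaluate_feature_prefix()].
#' @return List of class `prefix_scan`: `curve` (data frame
#'   length/accuracy/sensitivity/specificity/auc), `chosen_length`,
#'   and `ranked` (the input ranking).
#' @export
incremental_selection <- function(ranked, X, labels, max_prefix = 100L,
                                  folds = 4L, grid = default_rf_grid(),
                                  seed = 1L) {
  if (nrow(ranked) == 0L) stop("ranked feature list is empty", call. = FALSE)
  L <- min(max_prefix, nrow(ranked))
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(folds) == 1L) {
    folds <- make_stratified_folds(labels, as.integer(folds), seed = seed)
  }
  curve <- data.frame(length = seq_len(L), accuracy = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      auc = NA_real_)
  for (l in seq_len(L)) {
    cols <- ranked$column[seq_len(l)]
    m <- evaluate_feature_prefix(X[, cols, drop = FALSE], labels,
                                 folds = folds, grid = grid, seed = seed)
    curve$accuracy[l] <- m$accuracy
    curve$sensitivity[l] <- m$sensitivity
    curve$specificity[l] <- m$specificity
    curve$auc[l] <- m$auc
  }
  chosen <- which(curve$accuracy == max(curve$accuracy))[1L]
  out <- list(curve = curve, chosen_length = chosen, ranked = ranked)
  class(out) <- "prefix_scan"
  out
}

#' Fuse the optimal prefixes of both modalities
#'
#' Concatenates the chosen sMRI and fMRI ranked-feature prefixes into
#' one global feature vector and evaluates it with the same protocol
#' as [evaluate_feature_prefix()]. Both modalities must cover exactly
#' the same subjects (the fusion-eligible set).
#'
#' @param smri_scan,fmri_scan `prefix_scan` objects (or lists with
#'   `ranked` and `chosen_length`) for the two modalities.
#' @param X_smri,X_fmri Subjects x features matrices with identical
#'   rownames (subject ids) in identical order.
#' @param labels Class labels.
#' @param folds,grid,seed Passed to [evaluate_feature_prefix()].
#' @return List of class `fusion_model`: `metrics` (a `cv_metrics`),
#'   `fused_length`, `smri_prefix`, `fmri_prefix`.
#' @export
fuse_modalities <- function(smri_scan, fmri_scan, X_smri, X_fmri, labels,
                            folds = 4L, grid = default_rf_grid(),
                            seed = 1L) {
  if (smri_scan$chosen_length < 1L || fmri_scan$chosen_length < 1L) {
    stop("a modality prefix is empty", call. = FALSE)
  }
  if (!is.null(rownames(X_smri)) && !is.null(rownames(X_fmri)) &&
      !identical(rownames(X_smri), rownames(X_fmri))) {
    off <- union(setdiff(rownames(X_smri), rownames(X_fmri)),
                 setdiff(rownames(X_fmri), rownames(X_smri)))
    stop("subject sets differ between modalities: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  s_pref <- smri_scan$ranked[seq_len(smri_scan$chosen_length), ]
  f_pref <- fmri_scan$ranked[seq_len(fmri_scan$chosen_length), ]
  fused <- cbind(X_smri[, s_pref$column, drop = FALSE],
                 X_fmri[, f_pref$column, drop = FALSE])
  metrics <- evaluate_feature_prefix(fused, labels, folds = folds,
                                     grid = grid, seed = seed)
  out <- list(metrics = metrics,
              fused_length = nrow(s_pref) + nrow(f_pref),
              smri_prefix = s_pref, fmri_prefix = f_pref)
  class(out) <- "fusion_model"
  out
}

#' Compare classifier families on the fused features
#'
#' Applies the pipeline's cross-validation protocol to the fused
#' feature table with four classifier families: the grid-searched
#' random forest, a radial-kernel support-vector classifier, Gaussian
#' naive Bayes, and a single-hidden-layer feed-forward network
#' (8 units, weight decay 0.01, standardized inputs). All families
#' see the same features and folds.
#'
#' @param X Subjects x fused-features matrix.
#' @param labels Class labels.
#' @param folds,grid,seed As in [evaluate_feature_prefix()].
#' @return Data frame: one row per classifier with accuracy,
#'   sensitivity, specificity, AUC.
#' @export
benchmark_classifiers <- function(X, labels, folds = 4L,
                                  grid = default_rf_grid(), seed = 1L) {
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(folds) == 1L) {
    folds <- make_stratified_folds(labels, as.integer(folds), seed = seed)
  }
  families <- c(rf = "random_forest", svm = "svm", nb = "naive_bayes",
                nnet = "neural_network")
  rows <- lapply(names(families), function(cl) {
    m <- evaluate_feature_prefix(X, labels, folds = folds, grid = grid,
                                 seed = seed, classifier = cl)
    data.frame(classifier = families[[cl]], accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               auc = m$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
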