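#' Stratified cross-validation fold assignment
#'
#' Assigns subjects to `n_folds` folds, stratified by class so every
#' fold carries (as nearly as possible) the cohort's class balance.
#' Deterministic given the seed; every feature and both modalities use
#' one shared assignment.
#'
#' @param labels Factor or character vector of class labels.
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..n_folds.
#' @export
make_stratified_folds <- function(labels, n_folds = 4L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  fold <- integer(n)
  rng <- .local_rng(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop("class ", cl, " has fewer subjects (", length(idx),
           ") than folds (", n_folds, ")", call. = FALSE)
    }
    idx <- idx[order(rng(length(idx)))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Seeded uniform generator that does not disturb the global RNG state.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
}

#' Single-feature KNN autism probability
#'
#' The local classifier of the first pipeline stage: a k-nearest-
#' neighbour vote on one scalar pairwise feature. The autism
#' probability of a query is the fraction of its k nearest training
#' subjects (absolute distance on the feature value) labelled ASD; the
#' predicted label is the majority, with an exact 0.5 vote resolving
#' to TD as the conservative default. Distance ties are broken by a
#' seeded shuffle of the training order, so results are deterministic
#' given the seed.
#'
#' @param train_values Numeric vector of training feature values.
#' @param train_labels Labels (`"ASD"`/`"TD"`) matching `train_values`.
#' @param query_value Scalar (or vector) of query feature values.
#' @param k Neighbour count (default 7; must not exceed the training
#'   size).
#' @param seed Seed for the tie-break shuffle.
#' @return Numeric vector of autism probabilities (multiples of 1/k).
#' @export
knn_local_classifier <- function(train_values, train_labels,
                                 query_value, k = 7L, seed = 1L) {
  n <- length(train_values)
  if (length(train_labels) != n) {
    stop("train_values and train_labels lengths differ", call. = FALSE)
  }
  if (k > n) {
    stop("k (", k, ") exceeds the number of training subjects (", n, ")",
         call. = FALSE)
  }
  is_asd <- as.character(train_labels) == "ASD"
  rng <- .local_rng(seed)
  tie_rank <- order(rng(n))
  vapply(query_value, function(q) {
    d <- abs(train_values - q)
    nearest <- order(d, tie_rank)[seq_len(k)]
    sum(is_asd[nearest]) / k
  }, numeric(1))
}

#' Local KNN accuracy/probability grid over a feature matrix
#'
#' Runs the stage-1 local classification for every pairwise feature:
#' one KNN classifier per feature, evaluated out-of-fold under a
#' shared stratified fold assignment, yielding each feature's
#' cross-validated accuracy and each subject's out-of-fold autism
#' probability. With `resubstitution = TRUE` the classifiers are
#' instead trained and evaluated on the full cohort (training-set
#' accuracy; the subject itself is an eligible neighbour).
#'
#' @param X Subjects x features numeric matrix.
#' @param labels Class labels (`"ASD"`/`"TD"`), one per row of `X`.
#' @param folds Integer fold assignment from [make_stratified_folds()],
#'   or a fold count (default 4) to build one with `seed`.
#' @param k Neighbour count (default 7).
#' @param seed Seed for fold assignment and distance tie-breaks.
#' @param resubstitution Evaluate on the training set instead of
#'   out-of-fold.
#' @return List of class `local_grid`: `accuracy` (length-p vector),
#'   `prob` (n x p matrix of autism probabilities), `folds`, `k`.
#' @export
evaluate_local_grid <- function(X, labels, folds = 4L, k = 7L, seed = 1L,
                                resubstitution = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(labels) != n) stop("labels must match rows of X", call. = FALSE)
  if (length(folds) == 1L) {
    folds <- make_stratified_folds(labels, n_folds = as.integer(folds),
                                   seed = seed)
  }
  for (f in sort(unique(folds))) {
    if (length(unique(labels[folds == f])) < 2L) {
      stop("degenerate fold ", f, ": contains a single class", call. = FALSE)
    }
    if (any(table(labels[folds != f]) < 1L)) {
      stop("fold ", f, " leaves a training split with a single class",
           call. = FALSE)
    }
  }
  rng <- .local_rng(seed + 1L)
  tie_rank <- order(rng(n))
  res <- local_knn_grid_cpp(X, as.integer(labels == "ASD"),
                            as.integer(folds), as.integer(tie_rank),
                            as.integer(k), resubstitution)
  out <- list(accuracy = as.numeric(res$accuracy),
              prob = res$prob,
              folds = folds, k = k, labels = labels)
  if (!is.null(colnames(X))) names(out$accuracy) <- colnames(X)
  dimnames(out$prob) <- dimnames(X)
  class(out) <- "local_grid"
  out
}

#' Rank features by local cross-validated accuracy
#'
#' Orders the feature universe by descending local KNN accuracy. Ties
#' are broken lexicographically by (feature slab, i, j) — i.e. by
#' position in the canonical universe order — so the ranking is
#' deterministic.
#'
#' @param grid A `local_grid` from [evaluate_local_grid()], or a
#'   numeric accuracy vector.
#' @param index Feature universe matching the accuracy vector.
#' @return Data frame of class `ranked_features`: the index columns
#'   plus `accuracy` and `rank` (1 = best), sorted by rank.
#' @export
rank_features <- function(grid, index) {
  acc <- if (inherits(grid, "local_grid")) grid$accuracy else as.numeric(grid)
  if (length(acc) != nrow(index)) {
    stop("accuracy vector does not match the feature index", call. = FALSE)
  }
  ord <- order(-acc, seq_along(acc))   # universe order is (f, i, j)-lexicographic
  out <- index[ord, , drop = FALSE]
  out$accuracy <- acc[ord]
  out$rank <- seq_along(ord)
  out$column <- ord                    # column position in the feature matrix
  rownames(out) <- NULL
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Reshape one subject's local probabilities into matrix form
#'
#' Expands a subject's flat probability vector (one entry per
#' upper-triangle feature) into the symmetric 68 x 68 probability
#' matrix (fMRI) or 68 x 68 x 8 probability tensor (sMRI) with `NA` on
#' the diagonal, the form consumed by [build_personalized_map()].
#'
#' @param prob_row Numeric vector: one subject's row of
#'   `local_grid$prob`.
#' @param index Feature universe matching `prob_row`.
#' @return 68 x 68 matrix or 68 x 68 x 8 array with `NA` diagonals.
#' @export
subject_probability_structure <- function(prob_row, index) {
  modality <- index$modality[1L]
  if (modality == "fMRI") {
    P <- matrix(NA_real_, 68L, 68L)
    P[cbind(index$i, index$j)] <- prob_row
    P[cbind(index$j, index$i)] <- prob_row
    P
  } else {
    P <- array(NA_real_, dim = c(68L, 68L, 8L))
    P[cbind(index$i, index$j, index$f)] <- prob_row
    P[cbind(index$j, index$i, index$f)] <- prob_row
    P
  }
}
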