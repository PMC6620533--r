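#' Pairwise feature universe
#'
#' Enumerates the pairwise feature universe of one modality. Only the
#' strict upper triangle (i < j) of each matrix/slab is used: the
#' connectivity matrix is symmetric and each delta slab antisymmetric,
#' so the lower triangle duplicates the information (up to sign) and
#' the diagonal is constant (rho = 1, delta = 0) and carries none.
#' This gives 68*67/2 = 2278 functional-connectivity features and
#' 2278 * 8 = 18224 structural delta features.
#'
#' @param modality `"sMRI"` (pairs x 8 feature slabs, slab-major order)
#'   or `"fMRI"` (pairs only).
#' @return A data frame with columns `modality`, `i`, `j` (region
#'   indices, i < j) and `f` (slab index 1-8, `NA` for fMRI), ordered
#'   lexicographically by (f, i, j).
#' @export
feature_universe <- function(modality = c("sMRI", "fMRI")) {
  modality <- match.arg(modality)
  ut <- which(upper.tri(matrix(0, 68L, 68L)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  pairs <- data.frame(i = ut[, 1L], j = ut[, 2L])
  if (modality == "fMRI") {
    idx <- data.frame(modality = "fMRI", i = pairs$i, j = pairs$j,
                      f = NA_integer_, stringsAsFactors = FALSE)
  } else {
    idx <- do.call(rbind, lapply(seq_len(8L), function(f) {
      data.frame(modality = "sMRI", i = pairs$i, j = pairs$j, f = f,
                 stringsAsFactors = FALSE)
    }))
  }
  idx$feature_id <- feature_labels(idx)
  idx
}

#' Human-readable labels for feature indices
#'
#' @param index A feature-index data frame (columns `modality`, `i`,
#'   `j`, `f`).
#' @return Character vector like `"sMRI:FI:12-40"` or `"fMRI:3-17"`.
#' @export
feature_labels <- function(index) {
  feats <- morphometric_features()
  ifelse(index$modality == "sMRI",
         paste0("sMRI:", feats[index$f], ":", index$i, "-", index$j),
         paste0("fMRI:", index$i, "-", index$j))
}

#' Flatten a delta tensor to the sMRI feature vector
#'
#' @param delta 68 x 68 x 8 delta tensor from [build_delta_tensor()].
#' @param index Optional precomputed `feature_universe("sMRI")`.
#' @return Numeric vector of length 18224 in universe order.
#' @export
flatten_delta <- function(delta, index = feature_universe("sMRI")) {
  stopifnot(length(dim(delta)) == 3L, all(dim(delta) == c(68L, 68L, 8L)))
  unname(delta[cbind(index$i, index$j, index$f)])
}

#' Flatten a connectivity matrix to the fMRI feature vector
#'
#' @param cm 68 x 68 connectivity matrix from [connectivity_matrix()].
#' @param index Optional precomputed `feature_universe("fMRI")`.
#' @return Numeric vector of length 2278 in universe order.
#' @export
flatten_connectivity <- function(cm, index = feature_universe("fMRI")) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(68L, 68L)))
  unname(cm[cbind(index$i, index$j)])
}

#' Assemble a cohort feature matrix
#'
#' Stacks per-subject flattened feature vectors into the subjects x
#' features matrix consumed by the classification stages.
#'
#' @param objects Named list (names = subject ids) of delta tensors or
#'   connectivity matrices, all of one modality.
#' @param modality `"sMRI"` or `"fMRI"`.
#' @return List with `X` (subjects x features matrix, rownames =
#'   subject ids) and `index` (the feature universe).
#' @export
cohort_feature_matrix <- function(objects, modality = c("sMRI", "fMRI")) {
  modality <- match.arg(modality)
  index <- feature_universe(modality)
  flat <- if (modality == "sMRI") {
    vapply(objects, flatten_delta, numeric(nrow(index)), index = index)
  } else {
    vapply(objects, flatten_connectivity, numeric(nrow(index)),
           index = index)
  }
  X <- t(flat)
  rownames(X) <- names(objects)
  colnames(X) <- index$feature_id
  list(X = X, index = index)
}
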