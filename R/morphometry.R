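#' Per-vertex curvature-derived features
#'
#' Computes the four curvature-derived morphometric quantities from the
#' two principal curvatures of the cortical surface at each vertex:
#' mean-curvature index `MCI = (k1 + k2) / 2`, Gaussian curvature
#' `K = k1 * k2`, intrinsic curvature index `ICI = max(K, 0)` and
#' folding index `FI = |k1| * (|k1| - |k2|)`.
#'
#' The principal curvatures are reordered by magnitude (so that
#' `|k1| >= |k2|`) before the folding index is evaluated; with that
#' convention `FI >= 0` always holds, matching the behaviour of the
#' standard surface-reconstruction tools the feature definition comes
#' from. `MCI` and `K` are symmetric in (k1, k2) and unaffected.
#'
#' @param k1,k2 Numeric vectors of principal curvatures (1/mm),
#'   recycled to a common length.
#' @return A data frame with columns `MCI`, `K`, `ICI`, `FI`.
#' @examples
#' vertex_curvature_features(2, -1)  # MCI 0.5, K -2, ICI 0, FI 2
#' @export
vertex_curvature_features <- function(k1, k2) {
  k1 <- as.numeric(k1); k2 <- as.numeric(k2)
  n <- max(length(k1), length(k2))
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  if (!all(is.finite(k1)) || !all(is.finite(k2))) {
    stop("principal curvatures must be finite", call. = FALSE)
  }
  mci <- (k1 + k2) / 2
  gauss <- k1 * k2
  ici <- pmax(gauss, 0)
  a1 <- pmax(abs(k1), abs(k2))   # magnitude ordering: |k1| >= |k2|
  a2 <- pmin(abs(k1), abs(k2))
  fi <- a1 * (a1 - a2)
  data.frame(MCI = mci, K = gauss, ICI = ici, FI = fi)
}

#' Summarize vertex geometry into a region feature vector
#'
#' Aggregates a region's vertex-level geometry into the eight-feature
#' region summary: surface area `A` is the sum of per-vertex areas,
#' volume `V` is passed through from the volumetric segmentation,
#' `T_mean`/`T_sd` are the mean and sample (n-1) standard deviation of
#' vertex thickness, and the four curvature features are vertex
#' averages of [vertex_curvature_features()]. Averages are unweighted
#' by default; set `area_weighted = TRUE` to weight each vertex by its
#' surface area instead.
#'
#' @param vertices Data frame with columns `k1`, `k2`, `thickness`
#'   (mm, >= 0) and `vertex_area` (mm^2, >= 0); one row per vertex.
#' @param region_volume Region gray-matter volume in mm^3.
#' @param area_weighted Use area-weighted vertex averages for the
#'   thickness and curvature summaries (default `FALSE`).
#' @return Named numeric vector of length 8 in canonical feature order.
#' @export
summarize_region_features <- function(vertices, region_volume,
                                      area_weighted = FALSE) {
  req <- c("k1", "k2", "thickness", "vertex_area")
  if (!is.data.frame(vertices) || !all(req %in% names(vertices))) {
    stop("vertices must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(vertices) < 1L) stop("region has no vertices", call. = FALSE)
  if (any(vertices$vertex_area < 0) || any(vertices$thickness < 0)) {
    stop("vertex_area and thickness must be nonnegative", call. = FALSE)
  }
  curv <- vertex_curvature_features(vertices$k1, vertices$k2)
  if (area_weighted) {
    w <- vertices$vertex_area / sum(vertices$vertex_area)
    avg <- function(x) sum(w * x)
    t_mean <- avg(vertices$thickness)
    # weighted analogue of the sample SD (unbiased under equal weights)
    t_var <- sum(w * (vertices$thickness - t_mean)^2) /
      (1 - sum(w^2) + (nrow(vertices) == 1L))
    t_sd <- sqrt(max(t_var, 0))
  } else {
    avg <- mean
    t_mean <- mean(vertices$thickness)
    t_sd <- if (nrow(vertices) > 1L) sd(vertices$thickness) else 0
  }
  c(A = sum(vertices$vertex_area),
    V = as.numeric(region_volume),
    T_mean = t_mean,
    T_sd = t_sd,
    MCI = avg(curv$MCI),
    K = avg(curv$K),
    ICI = avg(curv$ICI),
    FI = avg(curv$FI))
}

#' Build a subject's pairwise-difference (delta) tensor
#'
#' For one subject's 68 x 8 region feature table, builds the
#' 68 x 68 x 8 tensor of signed pairwise differences
#' `delta[i, j, f] = feature_f(region_i) - feature_f(region_j)`.
#' Because each slab is a difference of region values, any quantity
#' added uniformly to a feature across all regions — a subject-level
#' confound such as overall head size — cancels exactly; the tensor is
#' antisymmetric in (i, j) with a zero diagonal.
#'
#' @param features 68 x 8 numeric matrix in canonical atlas/feature
#'   order, as returned by [read_region_features()].
#' @param atlas Atlas definition used to label the region axes.
#' @return A 68 x 68 x 8 array of class `delta_tensor` with dimnames
#'   `(region, region, feature)`.
#' @export
build_delta_tensor <- function(features, atlas = dk_atlas()) {
  validate_atlas(atlas)
  feats <- morphometric_features()
  if (!is.matrix(features) || nrow(features) != 68L ||
      ncol(features) != 8L) {
    stop("features must be a 68 x 8 matrix in atlas order", call. = FALSE)
  }
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), atlas$name)) {
    missing <- setdiff(atlas$name, rownames(features))
    if (length(missing)) {
      stop("missing region(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    features <- features[atlas$name, , drop = FALSE]
  }
  delta <- array(0, dim = c(68L, 68L, 8L),
                 dimnames = list(atlas$name, atlas$name, feats))
  for (f in seq_len(8L)) {
    v <- features[, f]
    delta[, , f] <- outer(v, v, "-")
  }
  class(delta) <- c("delta_tensor", class(delta))
  delta
}

#' Region feature table from a vertex-level table
#'
#' Builds the 68 x 8 region feature table from mesh-level inputs: a
#' vertex table (one row per vertex, with its region assignment and
#' geometry) and a per-region volume table from the volumetric
#' segmentation. Each region is summarized with
#' [summarize_region_features()].
#'
#' @param vertex_path CSV/TSV with columns
#'   `region, k1, k2, thickness, vertex_area`.
#' @param volume_path CSV/TSV with columns `region, V` (mm^3).
#' @param atlas Atlas definition.
#' @param area_weighted Passed to [summarize_region_features()].
#' @return A 68 x 8 matrix in canonical atlas/feature order, suitable
#'   for [build_delta_tensor()].
#' @export
region_features_from_vertices <- function(vertex_path, volume_path,
                                          atlas = dk_atlas(),
                                          area_weighted = FALSE) {
  validate_atlas(atlas)
  verts <- .read_delim(vertex_path)
  vols <- .read_delim(volume_path)
  req <- c("region", "k1", "k2", "thickness", "vertex_area")
  if (!all(req %in% names(verts))) {
    stop("vertex table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("region", "V") %in% names(vols))) {
    stop("volume table must have columns region, V", call. = FALSE)
  }
  match_region <- function(x) {
    if (is.numeric(x)) match(x, atlas$id) else match(trimws(as.character(x)), atlas$name)
  }
  verts$.r <- match_region(verts$region)
  if (anyNA(verts$.r)) {
    stop("unknown region(s) in vertex table: ",
         paste(unique(verts$region[is.na(verts$.r)]), collapse = ", "),
         call. = FALSE)
  }
  vol_r <- match_region(vols$region)
  vol_by_region <- rep(NA_real_, 68L)
  vol_by_region[vol_r[!is.na(vol_r)]] <- vols$V[!is.na(vol_r)]
  missing <- setdiff(seq_len(68L), unique(verts$.r))
  if (length(missing)) {
    stop("vertex table has no vertices for region(s): ",
         paste(atlas$name[missing], collapse = ", "), call. = FALSE)
  }
  if (anyNA(vol_by_region)) {
    stop("volume table is missing region(s): ",
         paste(atlas$name[is.na(vol_by_region)], collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(NA_real_, 68L, 8L,
                dimnames = list(atlas$name, morphometric_features()))
  for (r in seq_len(68L)) {
    out[r, ] <- summarize_region_features(verts[verts$.r == r, ],
                                          vol_by_region[r],
                                          area_weighted = area_weighted)
  }
  out
}
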