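#' Extract per-region mean time courses from a 4-D volume
#'
#' Masks a 4-D BOLD intensity array with an integer atlas labelmap and
#' returns, for every atlas region, the mean time course over the
#' voxels carrying that region's label. Voxel membership is by exact
#' label equality; no partial-volume weighting is applied.
#'
#' @param volume 4-D numeric array (x, y, z, t) of BOLD intensities.
#' @param labelmap 3-D integer array on the same spatial grid; values
#'   are atlas region ids (other values, e.g. 0 background, ignored).
#' @param atlas Atlas definition supplying the region ids and order.
#' @return A 68 x T matrix, rows in atlas order, rownames = region
#'   names.
#' @export
extract_mean_timecourses <- function(volume, labelmap, atlas = dk_atlas()) {
  validate_atlas(atlas)
  if (length(dim(volume)) != 4L) stop("volume must be 4-D", call. = FALSE)
  if (length(dim(labelmap)) != 3L) stop("labelmap must be 3-D", call. = FALSE)
  if (!identical(dim(volume)[1:3], dim(labelmap))) {
    stop("volume and labelmap spatial dimensions differ: ",
         paste(dim(volume)[1:3], collapse = "x"), " vs ",
         paste(dim(labelmap), collapse = "x"), call. = FALSE)
  }
  n_t <- dim(volume)[4L]
  n_vox <- prod(dim(labelmap))
  # flatten: rows = voxels, cols = time
  flat <- matrix(volume, nrow = n_vox, ncol = n_t)
  labels <- as.vector(labelmap)
  out <- matrix(NA_real_, nrow = 68L, ncol = n_t,
                dimnames = list(atlas$name, NULL))
  for (r in seq_len(68L)) {
    sel <- which(labels == atlas$id[r])
    if (!length(sel)) {
      stop("atlas region absent from labelmap: ", atlas$name[r],
           " (id ", atlas$id[r], ")", call. = FALSE)
    }
    out[r, ] <- colMeans(flat[sel, , drop = FALSE])
  }
  attr(out, "n_timepoints") <- n_t
  out
}

#' Read a BOLD volume and labelmap from NIfTI files
#'
#' Convenience wrapper that loads a 4-D BOLD NIfTI and a 3-D integer
#' labelmap NIfTI (via the RNifti package) and calls
#' [extract_mean_timecourses()].
#'
#' @param bold_path Path to the 4-D BOLD NIfTI file.
#' @param label_path Path to the 3-D integer labelmap NIfTI file.
#' @param atlas Atlas definition.
#' @return A 68 x T matrix of mean region time courses.
#' @export
extract_timecourses_nifti <- function(bold_path, label_path,
                                      atlas = dk_atlas()) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input", call. = FALSE)
  }
  vol <- RNifti::readNifti(bold_path)
  lab <- RNifti::readNifti(label_path)
  extract_mean_timecourses(array(vol, dim = dim(vol)),
                           array(round(lab), dim = dim(lab)), atlas)
}

#' Functional connectivity matrix
#'
#' Computes the 68 x 68 matrix of Pearson correlation coefficients
#' between all pairs of region time courses — the subject's functional
#' connectivity matrix. The result is symmetric with a unit diagonal
#' and entries in \[-1, 1\].
#'
#' A region with a constant time course has no defined correlation with
#' anything; by convention its off-diagonal entries are set to 0 (its
#' diagonal entry stays 1) and a warning is recorded, so one degenerate
#' region cannot abort a cohort run.
#'
#' @param timecourses 68 x T numeric matrix (rows = regions), T >= 3.
#' @param atlas Atlas definition used to label the output.
#' @return 68 x 68 numeric matrix of class `connectivity_matrix`, with
#'   attribute `constant_regions` naming any degenerate regions.
#' @export
connectivity_matrix <- function(timecourses, atlas = dk_atlas()) {
  validate_atlas(atlas)
  if (!is.matrix(timecourses) || nrow(timecourses) != 68L) {
    stop("timecourses must be a 68 x T matrix", call. = FALSE)
  }
  if (ncol(timecourses) < 3L) {
    stop("too few time points (T = ", ncol(timecourses), ")", call. = FALSE)
  }
  sds <- apply(timecourses, 1L, sd)
  const <- which(sds == 0)
  cm <- suppressWarnings(cor(t(timecourses)))
  if (length(const)) {
    cm[const, ] <- 0
    cm[, const] <- 0
    warning("constant time course in region(s): ",
            paste(atlas$name[const], collapse = ", "),
            "; their correlations set to 0")
  }
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2   # remove any floating-point asymmetry
  dimnames(cm) <- list(atlas$name, atlas$name)
  attr(cm, "constant_regions") <- atlas$name[const]
  class(cm) <- c("connectivity_matrix", class(cm))
  cm
}
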