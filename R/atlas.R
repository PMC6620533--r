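#' Desikan-Killiany cortical atlas definition
#'
#' Returns the canonical 68-region Desikan-Killiany (DK) cortical
#' parcellation used throughout the package: 34 cortical labels per
#' hemisphere, left hemisphere first, in FreeSurfer `aparc` label order.
#' All region-indexed inputs (feature tables, time-course matrices,
#' labelmaps) are validated against, and reordered to, this definition.
#'
#' Region ids are the FreeSurfer `aparc+aseg` integer codes (1001-1035
#' left, 2001-2035 right, the corpus-callosum placeholder 1004/2004
#' excluded), so an integer labelmap produced by the standard
#' surface-based parcellation can be used directly.
#'
#' @return A data frame of class `dk_atlas` with 68 rows and columns
#'   `id` (integer label code), `name` (e.g. `"lh-insula"`) and
#'   `hemisphere` (`"left"` or `"right"`).
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas)          # 68
#' table(atlas$hemisphere)
#' @export
dk_atlas <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
    "cuneus", "entorhinal", "fusiform", "inferiorparietal",
    "inferiortemporal", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole",
    "transversetemporal", "insula"
  )
  stopifnot(length(base) == 34L)
  # aparc codes skip the corpus-callosum slot (1004/2004)
  codes <- c(1001:1003, 1005:1035)
  atlas <- data.frame(
    id = c(codes, codes + 1000L),
    name = c(paste0("lh-", base), paste0("rh-", base)),
    hemisphere = rep(c("left", "right"), each = 34L),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("dk_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' Validate an atlas definition
#'
#' Checks the structural invariants every atlas used by this package
#' must satisfy: exactly 68 regions, unique ids and names, and 34
#' regions per hemisphere.
#'
#' @param atlas A `dk_atlas` data frame as returned by [dk_atlas()].
#' @return The atlas, invisibly, if valid; otherwise an error.
#' @export
validate_atlas <- function(atlas) {
  if (!is.data.frame(atlas) ||
      !all(c("id", "name", "hemisphere") %in% names(atlas))) {
    stop("atlas must be a data frame with columns id, name, hemisphere",
         call. = FALSE)
  }
  if (nrow(atlas) != 68L) {
    stop("atlas must define exactly 68 regions, got ", nrow(atlas),
         call. = FALSE)
  }
  if (anyDuplicated(atlas$id)) {
    stop("atlas region ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(atlas$name)) {
    stop("atlas region names must be unique", call. = FALSE)
  }
  tab <- table(atlas$hemisphere)
  if (!identical(sort(names(tab)), c("left", "right")) ||
      any(tab != 34L)) {
    stop("atlas must have 34 regions per hemisphere", call. = FALSE)
  }
  invisible(atlas)
}

#' Canonical morphometric feature names
#'
#' The eight region-level morphometric features, in canonical column
#' order: surface area (A, mm^2), volume (V, mm^3), mean cortical
#' thickness (T_mean, mm), thickness standard deviation (T_sd, mm),
#' mean-curvature index (MCI, 1/mm), Gaussian curvature (K, 1/mm^2),
#' intrinsic curvature index (ICI, 1/mm^2) and folding index
#' (FI, 1/mm^2).
#'
#' @return Character vector of length 8.
#' @export
morphometric_features <- function() {
  c("A", "V", "T_mean", "T_sd", "MCI", "K", "ICI", "FI")
}
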