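#' Build a subject's personalized per-area probability map
#'
#' Condenses a subject's local-classifier probabilities into two
#' 68-entry vectors — the personalized map. For every atlas area i,
#' `V_f(i)` is the maximum autism probability over all functional-
#' connectivity features involving i (`max_j P_F(i, j)`), and `V_s(i)`
#' the maximum over all structural delta features involving i and any
#' feature slab (`max_{j, f} P_S(i, j, f)`). The diagonal (i = j) is
#' excluded from the maxima: those entries are constant features and
#' carry no class information.
#'
#' @param P_F Subject's 68 x 68 functional probability matrix (as from
#'   [subject_probability_structure()]), or `NULL` if the subject has
#'   no fMRI.
#' @param P_S Subject's 68 x 68 x 8 structural probability tensor, or
#'   `NULL` if the subject has no sMRI.
#' @param subject_id Subject identifier stamped into the map.
#' @param atlas Atlas definition used to name the entries.
#' @return List of class `personalized_map` with `subject_id`, `V_f`
#'   and `V_s` (68-vectors named by region, `NULL` for an absent
#'   modality).
#' @export
build_personalized_map <- function(P_F = NULL, P_S = NULL,
                                   subject_id = NA_character_,
                                   atlas = dk_atlas()) {
  validate_atlas(atlas)
  row_max <- function(x) {
    if (all(is.na(x))) {
      stop("all entries excluded for an area; cannot take the maximum",
           call. = FALSE)
    }
    max(x, na.rm = TRUE)
  }
  V_f <- NULL
  if (!is.null(P_F)) {
    stopifnot(all(dim(P_F) == c(68L, 68L)))
    diag(P_F) <- NA_real_
    V_f <- setNames(apply(P_F, 1L, row_max), atlas$name)
  }
  V_s <- NULL
  if (!is.null(P_S)) {
    stopifnot(all(dim(P_S) == c(68L, 68L, 8L)))
    for (f in seq_len(dim(P_S)[3L])) {
      P_S[cbind(1:68, 1:68, f)] <- NA_real_
    }
    V_s <- setNames(apply(P_S, 1L, row_max), atlas$name)
  }
  if (is.null(V_f) && is.null(V_s)) {
    stop("at least one probability structure is required", call. = FALSE)
  }
  out <- list(subject_id = subject_id, V_f = V_f, V_s = V_s)
  class(out) <- "personalized_map"
  out
}

#' Personalized maps for a whole cohort
#'
#' Builds one [build_personalized_map()] per subject from the flat
#' local-grid probability matrices, without materializing all
#' per-subject probability tensors at once.
#'
#' @param fmri_grid,smri_grid `local_grid` objects from
#'   [evaluate_local_grid()] for the two modalities (either may be
#'   `NULL`).
#' @param fmri_index,smri_index Matching feature universes.
#' @param subject_ids Subject identifiers, one per grid row.
#' @return Named list of `personalized_map` objects.
#' @export
cohort_personalized_maps <- function(fmri_grid = NULL, smri_grid = NULL,
                                     fmri_index = NULL, smri_index = NULL,
                                     subject_ids, atlas = dk_atlas()) {
  n <- length(subject_ids)
  maps <- vector("list", n)
  names(maps) <- subject_ids
  for (s in seq_len(n)) {
    P_F <- if (!is.null(fmri_grid)) {
      subject_probability_structure(fmri_grid$prob[s, ], fmri_index)
    }
    P_S <- if (!is.null(smri_grid)) {
      subject_probability_structure(smri_grid$prob[s, ], smri_index)
    }
    maps[[s]] <- build_personalized_map(P_F, P_S, subject_ids[s], atlas)
  }
  maps
}

#' Export personalized maps as a table and colormap figures
#'
#' Writes all maps to one long-format CSV (`subject_id, region, V_f,
#' V_s`) and, optionally, one PNG per subject showing the 68 regions
#' as a 4 x 17 schematic grid coloured by autism probability (dark =
#' high). The schematic grid stands in for a cortical surface
#' rendering, which is out of scope here.
#'
#' @param maps List of `personalized_map` objects.
#' @param path Output directory (created if needed).
#' @param figures Also write per-subject PNG colormaps (default TRUE).
#' @param atlas Atlas definition.
#' @return Path of the written CSV, invisibly.
#' @export
export_map_table <- function(maps, path, figures = TRUE,
                             atlas = dk_atlas()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(maps, function(m) {
    data.frame(subject_id = m$subject_id,
               region = atlas$name,
               V_f = if (is.null(m$V_f)) NA_real_ else unname(m$V_f),
               V_s = if (is.null(m$V_s)) NA_real_ else unname(m$V_s),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  csv_path <- file.path(path, "personalized_maps.csv")
  write.csv(tab, csv_path, row.names = FALSE)
  if (figures) {
    for (m in maps) plot_personalized_map(m, dir = path)
  }
  invisible(csv_path)
}

#' Plot one personalized map as a schematic colormap
#'
#' @param map A `personalized_map`.
#' @param dir If non-`NULL`, write `map_<subject>.png` into this
#'   directory instead of drawing on the current device.
#' @param atlas Atlas definition.
#' @return Invisibly, the file path (or `NULL` when drawn on screen).
#' @export
plot_personalized_map <- function(map, dir = NULL, atlas = dk_atlas()) {
  pal <- grDevices::hcl.colors(64L, "YlOrRd", rev = TRUE)
  draw <- function(v, label) {
    grid_mat <- matrix(c(v, rep(NA_real_, 0L)), nrow = 4L, ncol = 17L)
    graphics::image(t(grid_mat), col = pal, zlim = c(0, 1), axes = FALSE,
                    main = paste0(map$subject_id, " - ", label))
  }
  out <- NULL
  panels <- sum(!is.null(map$V_f), !is.null(map$V_s))
  if (!is.null(dir)) {
    out <- file.path(dir, paste0("map_", map$subject_id, ".png"))
    grDevices::png(out, width = 900L, height = 260L * panels)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(panels, 1L), mar = c(1, 1, 2, 1))
  if (!is.null(map$V_s)) draw(map$V_s, "sMRI map (V_s)")
  if (!is.null(map$V_f)) draw(map$V_f, "fMRI map (V_f)")
  invisible(out)
}
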