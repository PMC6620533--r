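#' @useDynLib neurofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd rnorm runif quantile median pt pchisq
#' @importFrom utils read.table write.csv read.csv head
NULL

# Delimiter by extension: .tsv/.txt -> tab, anything else -> comma.
.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) "\t" else ","
}

.read_delim <- function(path) {
  read.table(path, header = TRUE, sep = .delim_for(path),
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Read and validate a cohort manifest
#'
#' Reads a delimited cohort manifest (one row per subject) and validates
#' it: subject ids must be unique, every subject must carry an ASD/TD
#' diagnosis label, and ADOS totals, when present, must be integers in
#' \[0, 30\]. All validation problems are collected and reported in a
#' single error so a malformed manifest can be fixed in one pass.
#'
#' Expected columns: `subject_id`, `label` (`ASD`/`TD`), `sex`
#' (`M`/`F`/`unknown`), `age` (years), `ados_total`, `ados_sa`,
#' `ados_rrb` (optional, may be blank), `has_smri`, `has_fmri`
#' (0/1 or TRUE/FALSE flags; assumed present when the column is
#' missing).
#'
#' @param path Path to a CSV/TSV manifest.
#' @param atlas Atlas definition (used only to stamp the manifest; the
#'   manifest itself carries no region information).
#' @return A data frame of class `cohort_manifest` with typed columns
#'   and logical `has_smri`/`has_fmri` flags.
#' @export
read_cohort_manifest <- function(path, atlas = dk_atlas()) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  validate_atlas(atlas)
  raw <- .read_delim(path)
  required <- c("subject_id", "label", "sex", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)

  ids <- as.character(raw$subject_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate subject_id: ",
                                   paste(dup, collapse = ", ")))
  }

  lab <- trimws(as.character(raw$label))
  bad_lab <- which(!lab %in% c("ASD", "TD"))
  if (length(bad_lab)) {
    problems <- c(problems,
                  paste0("row ", bad_lab, ": missing or invalid label '",
                         lab[bad_lab], "' (must be ASD or TD)"))
  }

  parse_ados <- function(col, lo, hi) {
    x <- raw[[col]]
    if (is.null(x)) return(rep(NA_integer_, nrow(raw)))
    x <- trimws(as.character(x))
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      problems <<- c(problems,
                     paste0("row ", bad, ": unparseable ", col, " value '",
                            x[bad], "'"))
    }
    frac <- which(!is.na(out) & out != round(out))
    if (length(frac)) {
      problems <<- c(problems,
                     paste0("row ", frac, ": non-integer ", col, " value"))
    }
    oob <- which(!is.na(out) & (out < lo | out > hi))
    if (length(oob)) {
      problems <<- c(problems,
                     paste0("row ", oob, ": ", col, " outside [", lo, ", ",
                            hi, "]"))
    }
    as.integer(round(out))
  }
  ados_total <- parse_ados("ados_total", 0, 30)
  ados_sa <- parse_ados("ados_sa", 0, 30)
  ados_rrb <- parse_ados("ados_rrb", 0, 30)

  age <- suppressWarnings(as.numeric(raw$age))
  bad_age <- which(is.na(age) | age < 0)
  if (length(bad_age)) {
    problems <- c(problems, paste0("row ", bad_age, ": invalid age"))
  }

  if (length(problems)) {
    stop("cohort manifest validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  sex <- trimws(as.character(raw$sex))
  sex[!sex %in% c("M", "F")] <- "unknown"
  as_flag <- function(col) {
    x <- raw[[col]]
    if (is.null(x)) return(rep(TRUE, nrow(raw)))
    if (is.numeric(x)) x != 0 else toupper(trimws(as.character(x))) %in%
      c("TRUE", "T", "1", "YES")
  }
  manifest <- data.frame(
    subject_id = ids,
    label = factor(lab, levels = c("TD", "ASD")),
    sex = sex,
    age = age,
    ados_total = ados_total,
    ados_sa = ados_sa,
    ados_rrb = ados_rrb,
    has_smri = as_flag("has_smri"),
    has_fmri = as_flag("has_fmri"),
    stringsAsFactors = FALSE
  )
  n_class <- table(manifest$label)
  if (any(n_class < 2L)) {
    warning("fewer than 2 subjects in class ",
            paste(names(n_class)[n_class < 2L], collapse = ", "),
            "; classification operations will refuse this cohort")
  }
  class(manifest) <- c("cohort_manifest", "data.frame")
  attr(manifest, "atlas") <- atlas
  manifest
}

#' Read a per-subject region feature table
#'
#' Reads one subject's 68 x 8 morphometric feature table and returns it
#' with rows in canonical atlas order regardless of the order on disk.
#' The first column must identify the region by atlas name (e.g.
#' `lh-insula`) or integer id; the remaining columns must be the eight
#' features in canonical order (see [morphometric_features()]).
#'
#' @param path CSV/TSV file with columns `region,A,V,T_mean,T_sd,MCI,K,ICI,FI`.
#' @param atlas Atlas definition.
#' @return A 68 x 8 numeric matrix, rownames = atlas region names,
#'   colnames = [morphometric_features()].
#' @export
read_region_features <- function(path, atlas = dk_atlas()) {
  validate_atlas(atlas)
  raw <- .read_delim(path)
  feats <- morphometric_features()
  missing_feats <- setdiff(feats, names(raw))
  if (length(missing_feats)) {
    stop("region feature table is missing feature column(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  region_col <- raw[[1L]]
  key <- if (is.numeric(region_col)) {
    match(region_col, atlas$id)
  } else {
    match(trimws(as.character(region_col)), atlas$name)
  }
  if (anyNA(key)) {
    stop("unknown region row(s): ",
         paste(region_col[is.na(key)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicated region row(s): ",
         paste(region_col[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(seq_len(68L), key)
  if (length(absent)) {
    stop("missing region(s): ", paste(atlas$name[absent], collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(raw[feats])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow(mat)))) & !is.na(mat), arr.ind = TRUE)
    stop("non-numeric feature value at row ", bad[1, 1], ", column ",
         feats[bad[1, 2]], call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("missing feature value at row ", bad[1, 1], ", column ",
         feats[bad[1, 2]], call. = FALSE)
  }
  out <- mat[order(key), , drop = FALSE]
  rownames(out) <- atlas$name
  colnames(out) <- feats
  out
}

#' Read a per-subject region time-course matrix
#'
#' Reads one subject's 68 x T matrix of mean BOLD time courses (rows =
#' regions, columns = time points) and reorders rows to canonical atlas
#' order. Regions with a constant (zero-variance) time course are
#' flagged in the `constant_regions` attribute because their Pearson
#' correlations are undefined downstream.
#'
#' @param path CSV file: 68 rows, first column the region name or id,
#'   remaining T columns the time points.
#' @param atlas Atlas definition.
#' @return A 68 x T numeric matrix with attributes `n_timepoints` and
#'   `constant_regions` (character vector, possibly empty).
#' @export
read_time_courses <- function(path, atlas = dk_atlas()) {
  validate_atlas(atlas)
  raw <- .read_delim(path)
  region_col <- raw[[1L]]
  key <- if (is.numeric(region_col)) {
    match(region_col, atlas$id)
  } else {
    match(trimws(as.character(region_col)), atlas$name)
  }
  if (anyNA(key)) {
    stop("unknown region row(s): ",
         paste(region_col[is.na(key)], collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(seq_len(68L), key)
  if (length(absent)) {
    stop("missing region(s): ", paste(atlas$name[absent], collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(raw[-1L])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric or missing time-course value", call. = FALSE)
  if (ncol(mat) < 3L) {
    stop("too few time points (T = ", ncol(mat), ", need at least 3)",
         call. = FALSE)
  }
  out <- mat[order(key), , drop = FALSE]
  rownames(out) <- atlas$name
  colnames(out) <- NULL
  const <- atlas$name[apply(out, 1L, function(x) diff(range(x)) == 0)]
  if (length(const)) {
    warning("constant time course in region(s): ",
            paste(const, collapse = ", "),
            "; correlations involving them are undefined")
  }
  attr(out, "n_timepoints") <- ncol(out)
  attr(out, "constant_regions") <- const
  out
}

#' Write a diagnosis report to JSON
#'
#' Serializes the result of a cohort run — per-subject predicted labels
#' and autism probabilities, the two personalized per-region probability
#' map vectors, and cohort-level accuracy/sensitivity/specificity/AUC —
#' to a machine-readable JSON report that [read_diagnosis_report()]
#' round-trips exactly.
#'
#' @param results A list with elements `subjects` (data frame with
#'   `subject_id`, `predicted_label`, `autism_probability`) and
#'   `metrics` (named list or data frame of cohort metrics, possibly
#'   per modality).
#' @param maps A list of personalized maps as built by
#'   [build_personalized_map()], or `NULL` when maps were not computed
#'   (the map fields are then null in the report).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnosis_report <- function(results, maps = NULL, path) {
  if (is.null(results$subjects) || is.null(results$metrics)) {
    stop("results must contain 'subjects' and 'metrics'", call. = FALSE)
  }
  map_block <- NULL
  if (!is.null(maps)) {
    map_block <- lapply(maps, function(m) {
      list(subject_id = m$subject_id,
           V_f = if (is.null(m$V_f)) NULL else unname(m$V_f),
           V_s = if (is.null(m$V_s)) NULL else unname(m$V_s))
    })
  }
  report <- list(
    format = "neurofuse-diagnosis-report",
    version = 1L,
    subjects = results$subjects,
    metrics = results$metrics,
    maps = map_block
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a diagnosis report written by [write_diagnosis_report()]
#'
#' @param path Path to the JSON report.
#' @return A list with `subjects`, `metrics` and `maps`.
#' @export
read_diagnosis_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(rep$format, "neurofuse-diagnosis-report")) {
    stop("not a neurofuse diagnosis report: ", path, call. = FALSE)
  }
  subjects <- do.call(rbind, lapply(rep$subjects, function(s) {
    data.frame(lapply(s, function(v) if (is.null(v)) NA else v),
               stringsAsFactors = FALSE)
  }))
  maps <- if (is.null(rep$maps)) NULL else lapply(rep$maps, function(m) {
    list(subject_id = m$subject_id,
         V_f = if (is.null(m$V_f)) NULL else as.numeric(unlist(m$V_f)),
         V_s = if (is.null(m$V_s)) NULL else as.numeric(unlist(m$V_s)))
  })
  list(subjects = subjects, metrics = rep$metrics, maps = maps)
}
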