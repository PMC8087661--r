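# Plain-text and NIfTI input/output for the pipeline's data objects.

#' Write / read one participant's ROI beta matrix as TSV
#'
#' Wide layout: one row per ROI, one column per task, first column `roi`.
#'
#' @param m A [roi_beta_matrix()].
#' @param path Output file.
#' @export
write_beta_matrix <- function(m, path) {
  df <- data.frame(roi = m$roi_names, m$values,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_beta_matrix
#' @param participant_id Identifier attached to the read matrix.
#' @export
read_beta_matrix <- function(path, participant_id = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  roi_beta_matrix(vals,
    roi_names = df[[1]], participant_id = participant_id,
    tasks = colnames(vals)
  )
}

#' Write / read participant group labels
#'
#' Two-column delimited file: `participant_id`, `group` (1 = patient,
#' 0 = control).
#'
#' @param ids Participant identifiers.
#' @param labels Binary labels.
#' @param path File path.
#' @export
write_labels <- function(ids, labels, path) {
  utils::write.table(
    data.frame(participant_id = ids, group = as.integer(labels)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(ids = as.character(df$participant_id), labels = as.integer(df$group))
}

#' Write / read a feature table as TSV plus a labels file
#'
#' The table file holds one row per feature (`feature` column followed by
#' one column per participant); labels travel in a companion file written
#' with [write_labels()].
#'
#' @param table A [feature_table()].
#' @param path Table file path; the labels file gets suffix `.labels.tsv`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature = table$feature_names, table$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_labels(table$participant_ids, table$labels,
    paste0(path, ".labels.tsv")
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @param family Family tag attached to the read table.
#' @export
read_feature_table <- function(path, family = "features") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- read_labels(paste0(path, ".labels.tsv"))
  vals <- as.matrix(df[, -1, drop = FALSE])
  feature_table(vals,
    feature_names = df[[1]], labels = lab$labels,
    family = family, participant_ids = lab$ids
  )
}

#' Write a synthetic configuration as structured text
#'
#' Key/value JSON with a `schema_version` field; loading patterns are
#' rebuilt deterministically from the stored seed on read.
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  snap <- config_snapshot(config)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(snap$schema_version) || snap$schema_version != 1L) {
    stop("unsupported config schema version", call. = FALSE)
  }
  config_from_snapshot(snap)
}

# Scalar-field snapshot of a synthetic_config (patterns are reproducible
# from the seed, so they are not serialized).
config_snapshot <- function(config) {
  list(
    schema_version = 1L,
    n_pos = config$n_pos, n_neg = config$n_neg,
    n_rois = config$n_rois, n_tasks = config$n_tasks,
    singular_values = config$singular_values,
    effect_rois = config$effect_rois,
    effect_size = config$effect_size,
    jitter_sd = config$jitter_sd,
    noise_sd = config$noise_sd,
    positivity_offset = config$positivity_offset,
    seed = config$seed,
    voxel_mode = config$voxel_mode,
    voxels_per_roi = config$voxels_per_roi,
    roi_names = config$roi_names
  )
}

config_from_snapshot <- function(snap) {
  synthetic_config(
    n_pos = snap$n_pos, n_neg = snap$n_neg,
    n_rois = snap$n_rois, n_tasks = snap$n_tasks,
    singular_values = snap$singular_values,
    effect_rois = snap$effect_rois,
    effect_size = snap$effect_size,
    jitter_sd = snap$jitter_sd,
    noise_sd = snap$noise_sd,
    positivity_offset = snap$positivity_offset,
    seed = snap$seed,
    voxel_mode = isTRUE(snap$voxel_mode),
    voxels_per_roi = snap$voxels_per_roi,
    roi_names = snap$roi_names
  )
}

#' Write / read a voxel volume as NIfTI
#'
#' Thin wrappers over RNifti for contrast volumes and integer label volumes.
#'
#' @param volume Numeric 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  dim(arr) <- dim(arr) # drop RNifti attributes via plain array copy
  arr
}

#' Coverage report across participants
#'
#' One row per ROI/task cell that failed the positive-voxel threshold in at
#' least one participant.
#'
#' @param matrices List of [roi_beta_matrix()] objects.
#' @return data.frame with columns `roi`, `task`, `n_uncovered`.
#' @export
coverage_report <- function(matrices) {
  roi_names <- matrices[[1L]]$roi_names
  tasks <- matrices[[1L]]$tasks
  counts <- Reduce(`+`, lapply(matrices, function(m) m$coverage * 1L))
  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(
      roi = character(0), task = character(0),
      n_uncovered = integer(0)
    ))
  }
  data.frame(
    roi = roi_names[idx[, 1]],
    task = tasks[idx[, 2]],
    n_uncovered = counts[idx],
    stringsAsFactors = FALSE
  )
}
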