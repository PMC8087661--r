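#' @keywords internal
mt_tasks <- function() c("picture", "sound", "stroop")

#' Construct a ROI beta-value matrix
#'
#' One participant's matrix of ROI mean beta values: rows are retained ROIs,
#' columns are task contrasts in the fixed order picture, sound, Stroop.
#' Values are nonnegative by construction (only positive supra-threshold
#' voxels enter the mean); a coverage flag marks ROI/task cells where no
#' voxel passed the threshold.
#'
#' @param values Numeric p x n matrix, nonnegative and finite.
#' @param roi_names Character vector of length p.
#' @param participant_id Scalar identifier.
#' @param coverage Logical p x n matrix (TRUE = no voxel passed the
#'   threshold); defaults to all FALSE.
#' @param tasks Character vector of column names, length n.
#' @return Object of class `roi_beta_matrix`.
#' @export
roi_beta_matrix <- function(values, roi_names = rownames(values),
                            participant_id = NA_character_,
                            coverage = NULL,
                            tasks = mt_tasks()[seq_len(ncol(values))]) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("`values` must be a finite numeric matrix", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("ROI beta values must be nonnegative", call. = FALSE)
  }
  if (is.null(roi_names) || length(roi_names) != nrow(values)) {
    stop("`roi_names` must have one entry per row", call. = FALSE)
  }
  if (length(tasks) != ncol(values)) {
    stop("`tasks` must have one entry per column", call. = FALSE)
  }
  if (is.null(coverage)) {
    coverage <- matrix(FALSE, nrow(values), ncol(values))
  }
  coverage <- as.matrix(coverage)
  stopifnot(identical(dim(coverage), dim(values)))
  dimnames(values) <- list(roi_names, tasks)
  dimnames(coverage) <- dimnames(values)
  structure(
    list(
      values = values,
      roi_names = as.character(roi_names),
      tasks = as.character(tasks),
      participant_id = participant_id,
      coverage = coverage
    ),
    class = "roi_beta_matrix"
  )
}

#' @export
print.roi_beta_matrix <- function(x, ...) {
  cat(sprintf(
    "ROI beta matrix [%s]: %d ROIs x %d tasks (%d uncovered cells)\n",
    x$participant_id, nrow(x$values), ncol(x$values), sum(x$coverage)
  ))
  invisible(x)
}

#' Mean beta of supra-threshold positive voxels in one ROI
#'
#' Implements the positive-voxel threshold rule: within the ROI, only voxels
#' strictly greater than 0.1 times the ROI maximum are averaged. Because the
#' maximum itself always passes when it is positive, a positive ROI always
#' yields a positive mean; when the ROI maximum is <= 0 (no positive signal)
#' the value is 0 and the coverage flag is set.
#'
#' @param contrast_volume Numeric array (or vector) of voxel beta values.
#' @param roi_mask Integer/logical index into `contrast_volume` selecting the
#'   ROI's voxels; must select at least one voxel.
#' @return List with `value` (nonnegative scalar) and `covered` (logical;
#'   FALSE when no voxel passed the threshold).
#' @export
#' @examples
#' extract_roi_value(c(1.0, 0.5, 0.09, -2.0), 1:4)  # mean of {1.0, 0.5}
extract_roi_value <- function(contrast_volume, roi_mask) {
  vox <- contrast_volume[roi_mask]
  if (length(vox) == 0L) {
    stop("ROI mask selects no voxels", call. = FALSE)
  }
  m <- max(vox)
  if (!is.finite(m) || m <= 0) {
    return(list(value = 0, covered = FALSE))
  }
  keep <- vox > 0.1 * m
  list(value = mean(vox[keep]), covered = TRUE)
}

#' Extract a participant's ROI beta matrix from contrast volumes
#'
#' Applies [extract_roi_value()] per ROI per task over a set of task-contrast
#' volumes sharing the atlas grid. Column order follows the order of
#' `volumes` (conventionally picture, sound, Stroop).
#'
#' @param volumes Named list of numeric arrays, one per task contrast, all on
#'   the same grid as the atlas label volume.
#' @param atlas An [atlas_labels()] object.
#' @param participant_id Identifier stored in the result.
#' @param apply_exclusions If TRUE (default) rows are restricted to the
#'   retained (non-excluded) regions; if FALSE all labelled regions are
#'   returned, which is the input expected by [filter_rois()] in coverage
#'   mode.
#' @return A [roi_beta_matrix()].
#' @export
extract_roibvals <- function(volumes, atlas, participant_id = NA_character_,
                             apply_exclusions = TRUE) {
  if (!inherits(atlas, "atlas_labels")) {
    stop("`atlas` must be an atlas_labels object", call. = FALSE)
  }
  if (!is.list(volumes) || length(volumes) < 1L) {
    stop("`volumes` must be a nonempty list of arrays", call. = FALSE)
  }
  for (v in volumes) {
    if (!identical(dim(v), dim(atlas$volume))) {
      stop("contrast volume grid does not match the atlas label volume",
        call. = FALSE
      )
    }
  }
  present <- sort(unique(as.integer(atlas$volume)))
  present <- present[present != 0L]
  unknown <- setdiff(present, atlas$labels$label)
  if (length(unknown) > 0L) {
    warning(sprintf(
      "ignoring %d unknown label value(s): %s",
      length(unknown), paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  roi_tab <- atlas$labels
  if (apply_exclusions) {
    roi_tab <- roi_tab[!(roi_tab$name %in% atlas$excluded), , drop = FALSE]
  }
  p <- nrow(roi_tab)
  n <- length(volumes)
  task_names <- names(volumes)
  if (is.null(task_names)) task_names <- mt_tasks()[seq_len(n)]
  vals <- matrix(0, p, n)
  cov <- matrix(FALSE, p, n)
  lab_vec <- as.integer(atlas$volume)
  for (i in seq_len(p)) {
    mask <- which(lab_vec == roi_tab$label[i])
    for (j in seq_len(n)) {
      if (length(mask) == 0L) {
        vals[i, j] <- 0
        cov[i, j] <- TRUE
        next
      }
      r <- extract_roi_value(volumes[[j]], mask)
      vals[i, j] <- r$value
      cov[i, j] <- !r$covered
    }
  }
  roi_beta_matrix(vals,
    roi_names = roi_tab$name, participant_id = participant_id,
    coverage = cov, tasks = task_names
  )
}

#' Select retained ROIs across participants
#'
#' Two policies for reducing the full atlas region set to the analysed ROIs:
#' `mode = "list"` drops the fixed exclusion list carried by the atlas
#' (78 retained under the defaults); `mode = "coverage"` drops any region
#' whose coverage flag is set for any task in any participant, a data-driven
#' alternative for datasets with unknown coverage.
#'
#' @param matrices List of [roi_beta_matrix()] objects sharing ROI order
#'   (required for `mode = "coverage"`; ignored for `mode = "list"`).
#' @param atlas An [atlas_labels()] object (or NULL for AAL-90 defaults).
#' @param mode `"list"` or `"coverage"`.
#' @return Character vector of retained ROI names in atlas order.
#' @export
filter_rois <- function(matrices = NULL, atlas = NULL,
                        mode = c("list", "coverage")) {
  mode <- match.arg(mode)
  if (mode == "list") {
    return(retained_roi_names(atlas))
  }
  if (is.null(matrices) || length(matrices) == 0L) {
    stop("coverage mode needs at least one participant matrix", call. = FALSE)
  }
  roi_names <- matrices[[1L]]$roi_names
  flagged <- rep(FALSE, length(roi_names))
  for (m in matrices) {
    if (!identical(m$roi_names, roi_names)) {
      stop("all matrices must share ROI ordering", call. = FALSE)
    }
    flagged <- flagged | apply(m$coverage, 1, any)
  }
  roi_names[!flagged]
}

#' Restrict ROI beta matrices to a set of retained ROIs
#'
#' @param matrices List of [roi_beta_matrix()] objects.
#' @param roi_names Names to retain, e.g. from [filter_rois()].
#' @return List of [roi_beta_matrix()] objects with rows subset in place.
#' @export
subset_rois <- function(matrices, roi_names) {
  lapply(matrices, function(m) {
    idx <- match(roi_names, m$roi_names)
    if (anyNA(idx)) {
      stop("some requested ROI names are absent from a participant matrix",
        call. = FALSE
      )
    }
    roi_beta_matrix(m$values[idx, , drop = FALSE],
      roi_names = roi_names,
      participant_id = m$participant_id,
      coverage = m$coverage[idx, , drop = FALSE],
      tasks = m$tasks
    )
  })
}
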