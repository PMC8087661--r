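#' AAL-90 cerebral region label table
#'
#' Returns the label-to-name mapping for the 90 cerebral regions of the
#' Automated Anatomical Labeling (AAL) parcellation, the region set used for
#' ROI mean-beta extraction. The table ships with the package as a plain
#' two-column file.
#'
#' @return A data.frame with integer column `label` (1..90) and character
#'   column `name`.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "mtpca")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$label <- as.integer(tab$label)
  tab
}

#' Default excluded AAL regions
#'
#' The 12 cerebral AAL regions dropped from analysis because their atlas
#' masks barely overlap typical task-fMRI coverage: bilateral olfactory
#' cortex, amygdala, superior parietal gyrus, paracentral lobule, middle
#' temporal pole and pallidum. Removing them from the 90 cerebral regions
#' leaves the 78 retained ROIs.
#'
#' @return Character vector of 12 region names.
#' @export
aal90_excluded <- function() {
  c(
    "Olfactory_L", "Olfactory_R",
    "Amygdala_L", "Amygdala_R",
    "Parietal_Sup_L", "Parietal_Sup_R",
    "Paracentral_Lobule_L", "Paracentral_Lobule_R",
    "Temporal_Pole_Mid_L", "Temporal_Pole_Mid_R",
    "Pallidum_L", "Pallidum_R"
  )
}

#' Construct an atlas-labels object
#'
#' Bundles an integer label volume with its label-to-name mapping and the
#' list of names excluded from analysis. Label 0 is background.
#'
#' @param label_volume Integer 3D array of voxel labels (0 = background).
#' @param label_names data.frame with columns `label`, `name`; defaults to
#'   [aal90_labels()].
#' @param excluded_names Character vector of excluded region names, a subset
#'   of `label_names$name`; defaults to [aal90_excluded()].
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(label_volume,
                         label_names = aal90_labels(),
                         excluded_names = aal90_excluded()) {
  if (!is.array(label_volume) || !is.numeric(label_volume)) {
    stop("`label_volume` must be a numeric/integer array", call. = FALSE)
  }
  if (any(label_volume < 0) || any(label_volume != floor(label_volume))) {
    stop("labels must be nonnegative integers (0 = background)", call. = FALSE)
  }
  if (!all(c("label", "name") %in% names(label_names))) {
    stop("`label_names` needs columns `label` and `name`", call. = FALSE)
  }
  if (!all(excluded_names %in% label_names$name)) {
    stop("`excluded_names` must be a subset of `label_names$name`", call. = FALSE)
  }
  structure(
    list(
      volume = label_volume,
      labels = label_names,
      excluded = excluded_names
    ),
    class = "atlas_labels"
  )
}

#' Names of ROIs retained under the exclusion list
#'
#' @param atlas An `atlas_labels` object, or NULL for the default AAL-90
#'   table with the default exclusions.
#' @return Character vector of retained region names in atlas order (78 under
#'   the defaults).
#' @export
retained_roi_names <- function(atlas = NULL) {
  if (is.null(atlas)) {
    nm <- aal90_labels()$name
    excl <- aal90_excluded()
  } else {
    nm <- atlas$labels$name
    excl <- atlas$excluded
  }
  setdiff(nm, excl)
}

#' @export
print.atlas_labels <- function(x, ...) {
  cat(sprintf(
    "Atlas labels: %d regions (%d excluded, %d retained), grid %s\n",
    nrow(x$labels), length(x$excluded),
    nrow(x$labels) - length(x$excluded),
    paste(dim(x$volume), collapse = " x ")
  ))
  invisible(x)
}
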