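# Per-participant PCA across task contrasts.
#
# The ROI-by-task matrix is treated with ROIs as observations (rows) and
# task contrasts as variables (columns): each column is centered by its own
# mean across ROIs, the matrix is divided by sqrt(n - 1), and the SVD is
# taken. The left singular vectors are the ROI-space component loadings used
# downstream as classification features; squared singular values normalized
# to sum one are the explained-variance proportions.

# Orient a vector so its largest-magnitude entry is positive (first
# occurrence breaks ties). Deterministic and invariant to the input sign.
orient_largest_positive <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Shared decomposition core for subject_pca() and voxel_pca().
pca_core <- function(X) {
  p <- nrow(X)
  n <- ncol(X)
  if (p <= n) stop("need more rows (observations) than columns", call. = FALSE)
  if (!all(is.finite(X))) stop("input matrix must be finite", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  Xs <- Xc / sqrt(n - 1)
  if (max(abs(Xs)) < 1e-12) {
    stop("degenerate input: zero variance after centering", call. = FALSE)
  }
  dec <- svd(Xs, nu = n, nv = n)
  U <- dec$u
  V <- dec$v
  for (k in seq_len(n)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(
    U = U, d = dec$d, V = V,
    proportions = dec$d^2 / sum(dec$d^2),
    scaled = Xs
  )
}

#' Per-participant PCA of a ROI-by-task beta matrix
#'
#' Centers each task column by its mean over ROIs, scales the matrix by
#' `1/sqrt(n - 1)` and decomposes it by SVD. Components are oriented so each
#' loading vector's largest-magnitude entry is positive; cross-participant
#' sign alignment is a separate step ([align_component_signs()]).
#'
#' @param X A [roi_beta_matrix()] or a numeric p x n matrix with p > n.
#' @param participant_id Identifier; taken from `X` when it is a
#'   [roi_beta_matrix()].
#' @return Object of class `subject_pca` with elements `components` (p x n
#'   matrix of ROI-space loadings, orthonormal columns), `singular_values`
#'   (descending), `explained_proportions` (descending, summing to 1),
#'   `scores` (n x n task-side matrix, the right singular vectors scaled by
#'   the singular values), `center` (the column means removed) and
#'   `participant_id`.
#' @export
#' @examples
#' X <- matrix(rexp(30), 10, 3)
#' fit <- subject_pca(X)
#' fit$explained_proportions
subject_pca <- function(X, participant_id = NULL) {
  roi_names <- NULL
  task_names <- NULL
  if (inherits(X, "roi_beta_matrix")) {
    roi_names <- X$roi_names
    task_names <- X$tasks
    if (is.null(participant_id)) participant_id <- X$participant_id
    X <- X$values
  }
  X <- as.matrix(X)
  core <- pca_core(X)
  n <- ncol(X)
  components <- core$U
  scores <- core$V %*% diag(core$d, nrow = n)
  rownames(components) <- if (!is.null(roi_names)) roi_names else rownames(X)
  rownames(scores) <- if (!is.null(task_names)) task_names else colnames(X)
  colnames(components) <- paste0("PC", seq_len(n))
  colnames(scores) <- paste0("PC", seq_len(n))
  structure(
    list(
      components = components,
      singular_values = core$d,
      explained_proportions = core$proportions,
      scores = scores,
      center = colMeans(X),
      participant_id = if (is.null(participant_id)) NA_character_ else participant_id
    ),
    class = "subject_pca"
  )
}

#' @export
print.subject_pca <- function(x, ...) {
  cat(sprintf(
    "Subject PCA [%s]: %d ROIs, %d components\n",
    x$participant_id, nrow(x$components), ncol(x$components)
  ))
  cat(
    "  explained proportions:",
    paste(sprintf("%.1f%%", 100 * x$explained_proportions), collapse = " / "),
    "\n"
  )
  invisible(x)
}

#' Align component signs across participants
#'
#' Eigenvector sign is mathematically indeterminate, so per-participant
#' loadings must share an orientation before they can be pooled as features.
#' Each participant's chosen component is first put in the canonical
#' per-subject orientation (largest-magnitude entry positive); the
#' elementwise median of those canonical vectors serves as the reference
#' direction, and any vector with a negative inner product against it is
#' flipped. The result depends only on the loadings up to sign, so the
#' operation is idempotent.
#'
#' @param pcas List of [subject_pca()] objects sharing the ROI dimension.
#' @param pc_index Component to align (1-based).
#' @return The list with the chosen component (and its score column)
#'   consistently oriented.
#' @export
align_component_signs <- function(pcas, pc_index) {
  p <- nrow(pcas[[1L]]$components)
  for (f in pcas) {
    if (nrow(f$components) != p) {
      stop("all participants must share the ROI dimension", call. = FALSE)
    }
  }
  canon <- vapply(
    pcas,
    function(f) orient_largest_positive(f$components[, pc_index]),
    numeric(p)
  )
  ref <- apply(canon, 1, stats::median)
  lapply(seq_along(pcas), function(j) {
    f <- pcas[[j]]
    v <- canon[, j]
    if (sum(v * ref) < 0) v <- -v
    # v equals the input component up to sign; flip the score column with it
    if (sum(v * f$components[, pc_index]) < 0) {
      f$scores[, pc_index] <- -f$scores[, pc_index]
    }
    f$components[, pc_index] <- v
    f
  })
}

#' Assemble the cross-participant loading feature matrix
#'
#' Stacks one component's loading vector per participant into a
#' features-by-participants matrix (78 x 40 under the study-sized defaults).
#' Sign alignment ([align_component_signs()]) should be applied first.
#'
#' @param pcas List of [subject_pca()] objects sharing ROI order.
#' @param pc_index Which component's loadings to use.
#' @param labels Binary group labels, one per participant.
#' @return A [feature_table()] with family tag `"PC<pc_index>"`.
#' @export
build_feature_matrix <- function(pcas, pc_index, labels) {
  p <- nrow(pcas[[1L]]$components)
  roi_names <- rownames(pcas[[1L]]$components)
  for (f in pcas) {
    if (nrow(f$components) != p) {
      stop("participants disagree on the ROI dimension", call. = FALSE)
    }
  }
  vals <- vapply(pcas, function(f) f$components[, pc_index], numeric(p))
  ids <- vapply(pcas, function(f) as.character(f$participant_id), character(1))
  feature_table(vals,
    feature_names = if (is.null(roi_names)) sprintf("ROI_%03d", seq_len(p)) else roi_names,
    labels = labels, family = paste0("PC", pc_index),
    participant_ids = ids
  )
}

#' Assemble a single-task ROI beta feature matrix
#'
#' Column j is participant j's ROI beta vector for the named task contrast,
#' giving the single-task baseline feature family against which the
#' component-loading features are compared.
#'
#' @param matrices List of [roi_beta_matrix()] objects sharing ROI order.
#' @param task Task name (`"picture"`, `"sound"` or `"stroop"`;
#'   case-insensitive).
#' @param labels Binary group labels.
#' @return A [feature_table()] with the task name as family tag.
#' @export
build_single_task_features <- function(matrices, task, labels) {
  tasks <- matrices[[1L]]$tasks
  j <- match(tolower(task), tolower(tasks))
  if (is.na(j)) {
    stop(sprintf(
      "unknown task \"%s\" (available: %s)", task,
      paste(tasks, collapse = ", ")
    ), call. = FALSE)
  }
  roi_names <- matrices[[1L]]$roi_names
  vals <- vapply(matrices, function(m) {
    if (!identical(m$roi_names, roi_names)) {
      stop("participants disagree on ROI ordering", call. = FALSE)
    }
    m$values[, j]
  }, numeric(length(roi_names)))
  ids <- vapply(matrices, function(m) as.character(m$participant_id), character(1))
  feature_table(vals,
    feature_names = roi_names, labels = labels,
    family = tasks[j], participant_ids = ids
  )
}

#' Group-wise summary of explained-variance proportions
#'
#' Mean, standard deviation and standard error of the explained-variance
#' percentage of each component, per group.
#'
#' @param pcas List of [subject_pca()] objects.
#' @param labels Binary group labels (1 = patient, 0 = control).
#' @return data.frame with columns `group`, `pc`, `n`, `mean`, `sd`, `sem`
#'   (percent scale).
#' @export
summarize_explained_variance <- function(pcas, labels) {
  stopifnot(length(pcas) == length(labels), is_binary01(labels))
  n_pc <- length(pcas[[1L]]$explained_proportions)
  props <- t(vapply(
    pcas, function(f) f$explained_proportions,
    numeric(n_pc)
  )) * 100
  out <- list()
  for (g in c(1L, 0L)) {
    sel <- which(labels == g)
    if (length(sel) < 2L) {
      stop("each group needs at least 2 participants for an SD", call. = FALSE)
    }
    sub <- props[sel, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      group = if (g == 1L) "patient" else "control",
      pc = paste0("PC", seq_len(n_pc)),
      n = length(sel),
      mean = colMeans(sub),
      sd = apply(sub, 2, stats::sd),
      sem = apply(sub, 2, stats::sd) / sqrt(length(sel)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Voxel-based PCA of mean task-contrast volumes
#'
#' The same decomposition as [subject_pca()], with masked voxels as
#' observations and task contrasts as variables; used to render group-level
#' component loading maps at voxel resolution for interpretation.
#'
#' @param mean_contrast_volumes Named list (>= 2) of numeric arrays on one
#'   grid, typically group-mean contrast images.
#' @param brain_mask Logical array on the same grid selecting voxels to
#'   include; NULL includes every voxel.
#' @return Object of class `voxel_pca`: `loadings` (voxels x components),
#'   `singular_values`, `explained_proportions`, `scores`, `mask`, and
#'   `maps`, a list of arrays (one per component) with loadings at in-mask
#'   voxels and NA elsewhere.
#' @export
voxel_pca <- function(mean_contrast_volumes, brain_mask = NULL) {
  n <- length(mean_contrast_volumes)
  if (n < 2L) stop("need at least 2 task volumes", call. = FALSE)
  dims <- dim(mean_contrast_volumes[[1L]])
  for (v in mean_contrast_volumes) {
    if (!identical(dim(v), dims)) {
      stop("volumes must share one grid", call. = FALSE)
    }
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dims)
  }
  if (!identical(dim(brain_mask), dims)) {
    stop("mask must share the volume grid", call. = FALSE)
  }
  idx <- which(brain_mask)
  if (length(idx) == 0L) stop("mask selects no voxels", call. = FALSE)
  X <- vapply(mean_contrast_volumes, function(v) v[idx], numeric(length(idx)))
  core <- pca_core(X)
  task_names <- names(mean_contrast_volumes)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(n))
  scores <- core$V %*% diag(core$d, nrow = n)
  rownames(scores) <- task_names
  colnames(scores) <- paste0("PC", seq_len(n))
  colnames(core$U) <- paste0("PC", seq_len(n))
  maps <- lapply(seq_len(n), function(k) {
    m <- array(NA_real_, dims)
    m[idx] <- core$U[, k]
    m
  })
  names(maps) <- paste0("PC", seq_len(n))
  structure(
    list(
      loadings = core$U,
      singular_values = core$d,
      explained_proportions = core$proportions,
      scores = scores,
      mask = brain_mask,
      maps = maps
    ),
    class = "voxel_pca"
  )
}

#' @export
print.voxel_pca <- function(x, ...) {
  cat(sprintf(
    "Voxel PCA: %d voxels, %d components; explained %s\n",
    nrow(x$loadings), ncol(x$loadings),
    paste(sprintf("%.1f%%", 100 * x$explained_proportions), collapse = " / ")
  ))
  invisible(x)
}
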