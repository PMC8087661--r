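# Synthetic two-group multitask ROI beta data.
#
# Each participant's ROI-by-task matrix is built as a low-rank product
# U_s diag(s) V' plus Gaussian noise, then shifted to be strictly positive.
# U_s is the participant's group loading-pattern set with a small random
# orthogonal jitter; V is a fixed orthonormal task-mixing matrix. Group
# patterns differ only in the second component, at a small set of effect
# ROIs, emulating a two-group difference in cross-task covariance structure.

# Fixed task-mixing matrix: deterministic constant, independent of the
# user's seed, so datasets with different seeds share the same task geometry.
fixed_task_mixing <- function(n_tasks) {
  M <- with_seed(
    20210430L,
    matrix(stats::rnorm(n_tasks * n_tasks), n_tasks, n_tasks)
  )
  orthonormalize(M)
}

# Orthonormal patterns in the orthogonal complement of the all-ones vector,
# so that column centering downstream leaves them untouched.
random_centered_patterns <- function(n_rois, n_tasks, seed) {
  Z <- with_seed(seed, matrix(stats::rnorm(n_rois * n_tasks), n_rois, n_tasks))
  Z <- sweep(Z, 2, colMeans(Z))
  orthonormalize(Z)
}

# Perturb component 2 of `U` at `effect_rois` by `effect_size`, then restore
# orthonormality. The perturbation direction has alternating signs over the
# effect ROIs (mean-zero when their count is even) and is centered so the
# patterns stay orthogonal to the ones vector.
perturb_component2 <- function(U, effect_rois, effect_size) {
  p <- nrow(U)
  d <- numeric(p)
  k <- length(effect_rois)
  d[effect_rois] <- rep_len(c(1, -1), k) / sqrt(k)
  d <- d - mean(d)
  v <- U[, 2] + effect_size * d
  others <- setdiff(seq_len(ncol(U)), 2L)
  for (j in others) v <- v - sum(U[, j] * v) * U[, j]
  U[, 2] <- v / sqrt(sum(v^2))
  U
}

#' Configuration for the synthetic multitask ROI generator
#'
#' Defines a two-group study: `n_pos` patients (label 1) and `n_neg` controls
#' (label 0), each contributing one `n_rois` x `n_tasks` ROI beta matrix with
#' a shared rank-`n_tasks` cross-task covariance structure. The groups share
#' components 1 and 3; the component-2 loading pattern of the patient group
#' is perturbed at `effect_rois` by `effect_size`, so the planted group
#' difference lives in the second component's loadings.
#'
#' Defaults emulate a small two-group task-fMRI study: 19 patients vs 21
#' controls, 78 retained cerebral ROIs, 3 task contrasts, singular-value
#' shares 70/20/10 percent, and six effect ROIs (bilateral inferior frontal
#' gyrus pars orbitalis, right calcarine, right lingual, left inferior
#' occipital, left inferior temporal).
#'
#' @param n_pos,n_neg Group sizes (>= 1).
#' @param n_rois Number of ROIs (>= n_tasks).
#' @param n_tasks Number of task contrasts (>= 2).
#' @param singular_values Nonnegative scales of the components; squared and
#'   normalized they are the zero-noise explained-variance proportions.
#' @param group_loading_patterns Optional list with elements `pos` and `neg`,
#'   each an `n_rois` x `n_tasks` matrix with orthonormal, column-centered
#'   columns. By default patterns are built deterministically from `seed`.
#' @param effect_rois Integer indices of ROIs where the groups' component-2
#'   loadings differ; default the six named regions above (when
#'   `n_rois = 78`) or the first six ROIs otherwise.
#' @param effect_size Magnitude of the component-2 loading perturbation.
#' @param jitter_sd Standard deviation of the per-participant orthogonal
#'   jitter applied to the group patterns (between-subject variability).
#' @param noise_sd Standard deviation of additive Gaussian entry noise (>= 0).
#' @param positivity_offset Constant added after shifting so the smallest
#'   matrix entry equals this value (> 0).
#' @param seed Master seed; all randomness derives from it.
#' @param voxel_mode If TRUE, [generate_volumes()] may be used to emit
#'   labelled voxel volumes for this configuration.
#' @param voxels_per_roi Voxels per ROI in voxel mode (>= 3).
#' @param roi_names Optional ROI names; defaults to the retained AAL-90
#'   names when `n_rois = 78`.
#' @return Object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' cfg
synthetic_config <- function(n_pos = 19, n_neg = 21,
                             n_rois = 78, n_tasks = 3,
                             singular_values = sqrt(c(0.70, 0.20, 0.10)),
                             group_loading_patterns = NULL,
                             effect_rois = NULL,
                             effect_size = 0.4,
                             jitter_sd = 0.08,
                             noise_sd = 0.02,
                             positivity_offset = 0.05,
                             seed = 1L,
                             voxel_mode = FALSE,
                             voxels_per_roi = 5L,
                             roi_names = NULL) {
  n_pos <- stop_if_not_count(n_pos, "n_pos")
  n_neg <- stop_if_not_count(n_neg, "n_neg")
  n_rois <- stop_if_not_count(n_rois, "n_rois", min = 2L)
  n_tasks <- stop_if_not_count(n_tasks, "n_tasks", min = 2L)
  if (n_rois < n_tasks) stop("`n_rois` must be >= `n_tasks`", call. = FALSE)
  if (length(singular_values) != n_tasks || any(singular_values < 0)) {
    stop("`singular_values` must be ", n_tasks, " nonnegative reals",
      call. = FALSE
    )
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single real >= 0", call. = FALSE)
  }
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  if (positivity_offset <= 0) stop("`positivity_offset` must be > 0", call. = FALSE)
  seed <- as.integer(seed)

  if (is.null(roi_names)) {
    roi_names <- if (n_rois == 78L) {
      retained_roi_names()
    } else {
      sprintf("ROI_%03d", seq_len(n_rois))
    }
  }
  stopifnot(length(roi_names) == n_rois)

  if (is.null(effect_rois)) {
    if (n_rois == 78L) {
      eff_names <- c(
        "Frontal_Inf_Orb_L", "Frontal_Inf_Orb_R", "Calcarine_R",
        "Lingual_R", "Occipital_Inf_L", "Temporal_Inf_L"
      )
      effect_rois <- match(eff_names, roi_names)
    } else {
      effect_rois <- seq_len(min(6L, n_rois))
    }
  }
  effect_rois <- as.integer(effect_rois)
  if (any(is.na(effect_rois)) || any(effect_rois < 1L) ||
    any(effect_rois > n_rois)) {
    stop("`effect_rois` must be indices in 1..n_rois", call. = FALSE)
  }

  if (is.null(group_loading_patterns)) {
    base <- random_centered_patterns(n_rois, n_tasks, derive_seed(seed, 1L))
    pos <- if (effect_size > 0 && n_tasks >= 2) {
      perturb_component2(base, effect_rois, effect_size)
    } else {
      base
    }
    group_loading_patterns <- list(pos = pos, neg = base)
  }
  for (g in c("pos", "neg")) {
    U <- group_loading_patterns[[g]]
    if (is.null(U) || !is.matrix(U) ||
      !identical(dim(U), c(n_rois, n_tasks))) {
      stop("group loading patterns must be n_rois x n_tasks matrices",
        call. = FALSE
      )
    }
    G <- crossprod(U)
    if (max(abs(G - diag(n_tasks))) > 1e-8) {
      stop("loading patterns must be unit-norm and mutually orthogonal",
        call. = FALSE
      )
    }
  }

  structure(
    list(
      n_pos = n_pos, n_neg = n_neg, n_rois = n_rois, n_tasks = n_tasks,
      singular_values = as.numeric(singular_values),
      group_loading_patterns = group_loading_patterns,
      effect_rois = effect_rois, effect_size = effect_size,
      jitter_sd = jitter_sd, noise_sd = noise_sd,
      positivity_offset = positivity_offset,
      seed = seed, voxel_mode = isTRUE(voxel_mode),
      voxels_per_roi = as.integer(voxels_per_roi),
      roi_names = roi_names,
      task_mixing = fixed_task_mixing(n_tasks)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic config: %d + %d participants, %d ROIs x %d tasks\n",
    x$n_pos, x$n_neg, x$n_rois, x$n_tasks
  ))
  cat(sprintf(
    "  singular values %s | effect at %d ROIs (size %.2f) | jitter %.3f, noise %.3f | seed %d\n",
    paste(signif(x$singular_values, 3), collapse = "/"),
    length(x$effect_rois), x$effect_size, x$jitter_sd, x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic two-group multitask ROI dataset
#'
#' Builds one ROI beta matrix per participant as
#' `U_s diag(s) V' + noise`, where `U_s` is the participant's group
#' loading-pattern set with per-subject orthogonal jitter, `V` the fixed
#' task-mixing matrix and the noise i.i.d. Gaussian, then shifts every
#' matrix so all entries are strictly positive (mirroring positive-voxel
#' averaging upstream). Identical seeds produce identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: list with `beta_matrices`
#'   (list of [roi_beta_matrix()]), `labels` (1 = patient, 0 = control),
#'   `participant_ids`, and `truth` (the configuration used).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_pos = 3, n_neg = 3, n_rois = 10, seed = 1))
#' length(ds$beta_matrices)
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  m <- config$n_pos + config$n_neg
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  ids <- sprintf("S%03d", seq_len(m))
  S <- diag(config$singular_values, nrow = config$n_tasks)
  V <- config$task_mixing
  mats <- vector("list", m)
  for (i in seq_len(m)) {
    U_g <- if (labels[i] == 1L) {
      config$group_loading_patterns$pos
    } else {
      config$group_loading_patterns$neg
    }
    subject_seed <- derive_seed(config$seed, 100L + i)
    X <- with_seed(subject_seed, {
      U_s <- U_g
      if (config$jitter_sd > 0) {
        Z <- matrix(
          stats::rnorm(config$n_rois * config$n_tasks),
          config$n_rois, config$n_tasks
        )
        Z <- sweep(Z, 2, colMeans(Z))
        U_s <- orthonormalize(U_g + config$jitter_sd * Z)
      }
      X <- U_s %*% S %*% t(V)
      if (config$noise_sd > 0) {
        X <- X + matrix(
          stats::rnorm(length(X), sd = config$noise_sd),
          nrow(X), ncol(X)
        )
      }
      X
    })
    X <- X - min(X) + config$positivity_offset
    mats[[i]] <- roi_beta_matrix(X,
      roi_names = config$roi_names,
      participant_id = ids[i]
    )
  }
  structure(
    list(
      beta_matrices = mats,
      labels = labels,
      participant_ids = ids,
      truth = config
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d participants (%d/%d), %d ROIs x %d tasks, seed %d\n",
    length(x$beta_matrices), sum(x$labels == 1), sum(x$labels == 0),
    x$truth$n_rois, x$truth$n_tasks, x$truth$seed
  ))
  invisible(x)
}

#' Emit labelled voxel volumes realizing a ROI beta matrix
#'
#' Builds a toy integer label volume over the full atlas label set and, per
#' task, a voxel beta volume whose supra-threshold positive-voxel mean per
#' retained ROI equals the requested ROI beta value. Each retained ROI gets
#' `voxels_per_roi` voxels: signal voxels whose mean is the target, plus one
#' planted sub-threshold voxel and one negative voxel to exercise the
#' threshold rule. Excluded atlas regions receive no positive voxels, so
#' extraction flags them as uncovered.
#'
#' @param config A [synthetic_config()] with `voxel_mode = TRUE` and
#'   `voxels_per_roi >= 3`.
#' @param beta A [roi_beta_matrix()] whose ROI names are all present in the
#'   atlas table.
#' @param atlas_table data.frame of all atlas labels/names; defaults to
#'   [aal90_labels()] when the config uses the default 78 ROI names.
#' @param excluded_names Names treated as excluded; default [aal90_excluded()]
#'   under the default atlas, otherwise none.
#' @return List with `atlas` (an [atlas_labels()] holding the label volume)
#'   and `volumes` (named list of per-task voxel arrays).
#' @export
generate_volumes <- function(config, beta, atlas_table = NULL,
                             excluded_names = NULL) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  if (!isTRUE(config$voxel_mode)) {
    stop("voxel mode is not enabled in this configuration", call. = FALSE)
  }
  if (config$voxels_per_roi < 3L) {
    stop("`voxels_per_roi` must be >= 3", call. = FALSE)
  }
  if (is.null(atlas_table)) {
    if (all(beta$roi_names %in% aal90_labels()$name)) {
      atlas_table <- aal90_labels()
      if (is.null(excluded_names)) excluded_names <- aal90_excluded()
    } else {
      atlas_table <- data.frame(
        label = seq_along(beta$roi_names),
        name = beta$roi_names, stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(excluded_names)) excluded_names <- character(0)
  if (!all(beta$roi_names %in% atlas_table$name)) {
    stop("beta ROI names must all appear in the atlas table", call. = FALSE)
  }

  vpr <- config$voxels_per_roi
  nlab <- nrow(atlas_table)
  dims <- c(vpr, nlab, 1L)
  label_vol <- array(0L, dims)
  for (j in seq_len(nlab)) label_vol[, j, 1] <- atlas_table$label[j]

  volumes <- lapply(seq_along(beta$tasks), function(tj) {
    vol <- array(0, dims)
    for (j in seq_len(nlab)) {
      nm <- atlas_table$name[j]
      if (nm %in% excluded_names) next # leave sub-threshold (all zero)
      ri <- match(nm, beta$roi_names)
      if (is.na(ri)) next
      b <- beta$values[ri, tj]
      if (b <= 0) next # uncovered ROI: no positive voxels
      ns <- vpr - 2L
      signal <- if (ns <= 1L) {
        b
      } else {
        # symmetric spread around b keeps the survivor mean exactly b;
        # smallest signal voxel 0.5*b stays above 0.1 * max (= 0.15*b)
        delta <- rep_len(c(0.5, -0.5), ns)
        if (ns %% 2L == 1L) delta[ns] <- 0
        b * (1 + delta)
      }
      m <- max(signal)
      vox <- c(signal, 0.05 * m, -b) # sub-threshold + negative distractors
      vol[seq_along(vox), j, 1] <- vox
    }
    vol
  })
  names(volumes) <- beta$tasks

  list(
    atlas = atlas_labels(label_vol,
      label_names = atlas_table,
      excluded_names = excluded_names
    ),
    volumes = volumes
  )
}
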