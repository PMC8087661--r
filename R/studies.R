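# Multi-seed simulation studies over the synthetic generator: parameter
# recovery of the planted effect ROIs by LASSO, dominance of the
# component-2 loading features over single-task baselines, and the
# explained-variance regime of the generator. Deterministic given a base
# seed; per-replicate seeds are base_seed + replicate index.

#' Planted-ROI recovery rate of LASSO selection on component-2 loadings
#'
#' For each replicate, a study-sized two-group dataset is generated with the
#' group difference planted in the component-2 loadings at the configured
#' effect ROIs; per-participant PCA, sign alignment and the component-2
#' feature matrix are built; and LASSO selection with LOOCV deviance is run.
#' A replicate counts as a recovery when at least one planted ROI appears
#' among the selected features.
#'
#' @param n_seeds Number of replicates (default 50).
#' @param base_seed Master seed; replicate r uses `base_seed + r`.
#' @param ... Overrides passed to [synthetic_config()].
#' @return List with `rate` (fraction of replicates recovering a planted
#'   ROI), `n_selected` (per-replicate selected-feature counts) and
#'   `n_planted_selected` (per-replicate planted-ROI hits).
#' @export
selection_rate_study <- function(n_seeds = 50L, base_seed = 1L, ...) {
  hits <- logical(n_seeds)
  n_selected <- integer(n_seeds)
  n_planted <- integer(n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- synthetic_config(seed = base_seed + r, ...)
    ds <- generate_dataset(cfg)
    pcas <- lapply(ds$beta_matrices, subject_pca)
    pcas <- align_component_signs(pcas, 2L)
    tab <- build_feature_matrix(pcas, 2L, ds$labels)
    path <- select_lambda_loocv(tab)
    planted <- cfg$roi_names[cfg$effect_rois]
    sel <- path$selected_features
    n_selected[r] <- length(sel)
    n_planted[r] <- length(intersect(sel, planted))
    hits[r] <- n_planted[r] >= 1L
  }
  list(
    rate = mean(hits),
    n_selected = n_selected,
    n_planted_selected = n_planted
  )
}

#' Dominance of component-2 features over single-task baselines
#'
#' For each replicate, the full pipeline (selection then RBF-SVM LOOCV) is
#' run for the component-2 loading family and each single-task ROI beta
#' family with an identical grid and fold scheme; the replicate counts as a
#' dominance when the component-2 LOOCV accuracy is at least that of every
#' single-task family.
#'
#' @param n_seeds Number of replicates (default 25).
#' @param base_seed Master seed; replicate r uses `base_seed + r`.
#' @param svm An [svm_config()] shared by every family and replicate.
#' @param ... Overrides passed to [synthetic_config()].
#' @return List with `rate` (fraction of replicates where the component-2
#'   family dominates) and `accuracies` (replicates x families data.frame of
#'   exact LOOCV accuracies).
#' @export
family_dominance_study <- function(n_seeds = 25L, base_seed = 1L,
                                   svm = svm_config(), ...) {
  fams <- c("PC2", "picture", "sound", "stroop")
  acc <- matrix(NA_real_, n_seeds, length(fams),
    dimnames = list(NULL, fams)
  )
  for (r in seq_len(n_seeds)) {
    cfg <- synthetic_config(seed = base_seed + r, ...)
    ds <- generate_dataset(cfg)
    fam <- build_family_tables(ds$beta_matrices, ds$labels)
    cmp <- compare_feature_sets(fam$tables[fams],
      config = svm,
      seed = cfg$seed
    )
    acc[r, ] <- vapply(
      cmp$results[fams],
      function(x) x$svm$accuracy, numeric(1)
    )
  }
  dominated <- acc[, "PC2"] >= apply(acc[, -1, drop = FALSE], 1, max)
  list(
    rate = mean(dominated),
    accuracies = as.data.frame(acc)
  )
}

#' Explained-variance regime of the synthetic generator
#'
#' Generates one study-sized dataset, runs per-participant PCA, and returns
#' the group-wise mean explained-variance percentages — the quantity that,
#' with singular-value shares (0.70, 0.20, 0.10), should sit near
#' 70/20/10.
#'
#' @param seed Generator seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return List with `summary` (the [summarize_explained_variance()] table)
#'   and `group_means` (groups x components matrix of mean percentages).
#' @export
variance_regime_study <- function(seed = 1L, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  ds <- generate_dataset(cfg)
  pcas <- lapply(ds$beta_matrices, subject_pca)
  summ <- summarize_explained_variance(pcas, ds$labels)
  gm <- do.call(rbind, lapply(split(summ, summ$group), function(d) {
    stats::setNames(d$mean, d$pc)
  }))
  list(summary = summ, group_means = gm)
}
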