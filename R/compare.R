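# Select -> classify -> metrics per feature family, with a shared SVM grid
# and fold scheme, mirroring the comparison of component-loading features
# against the single-task baselines.

drop_participant <- function(table, i) {
  feature_table(table$values[, -i, drop = FALSE],
    feature_names = table$feature_names,
    labels = table$labels[-i], family = table$family,
    participant_ids = table$participant_ids[-i]
  )
}

# Feature set for classification: the minimum-deviance LASSO selection, or,
# when that is the null model, the earliest-entering feature(s) on the path
# (largest penalty with any nonzero coefficient).
classification_features <- function(table, path_obj) {
  feats <- path_obj$selected_features
  if (length(feats) > 0L) {
    return(feats)
  }
  full <- lasso_logistic_path(table, path_obj$lambdas)
  nz_per_lambda <- colSums(full$coefficients != 0)
  first <- which(nz_per_lambda > 0)[1L]
  if (is.na(first)) {
    return(table$feature_names)
  }
  coefs <- full$coefficients[, first]
  nz <- which(coefs != 0)
  table$feature_names[nz[order(abs(coefs[nz]), decreasing = TRUE)]]
}

# One family through the default (non-nested) topology: LASSO selection on
# the full sample, then SVM LOOCV on the selected features. This replicates
# the published procedure; selection sees every participant, so held-out
# folds are not independent of it (see nested_svm_loocv for the honest
# variant).
classify_family_pooled <- function(table, config, seed) {
  path_obj <- select_lambda_loocv(table)
  feats <- classification_features(table, path_obj)
  svm_fit <- svm_grid_search_loocv(subset_features(table, feats),
    config = config, seed = seed
  )
  cm <- confusion_from_predictions(svm_fit$predictions, table$labels)
  list(
    family = table$family,
    path = path_obj,
    features = feats,
    svm = svm_fit,
    confusion = cm,
    metrics = compute_metrics(cm)
  )
}

#' Nested-cross-validation SVM metrics for one feature family
#'
#' Honest error estimation: for each held-out participant, the LASSO
#' penalty/feature selection *and* the SVM (C, gamma) grid search are re-run
#' on the remaining participants only, so no information about the held-out
#' case leaks into either choice.
#'
#' @param table A [feature_table()].
#' @param config An [svm_config()] for the inner grid search.
#' @param seed Recorded seed (the procedure is deterministic).
#' @return List with pooled `predictions`, `confusion`, `metrics`, and
#'   per-fold selections (`features`, `C`, `gamma`).
#' @export
nested_svm_loocv <- function(table, config = svm_config(), seed = 1L) {
  check_two_classes(table)
  m <- ncol(table$values)
  if (m < 5L) stop("nested LOOCV needs at least 5 participants", call. = FALSE)
  preds <- integer(m)
  fold_info <- vector("list", m)
  for (i in seq_len(m)) {
    inner <- drop_participant(table, i)
    path_obj <- select_lambda_loocv(inner)
    feats <- classification_features(inner, path_obj)
    inner_sel <- subset_features(inner, feats)
    gs <- svm_grid_search_loocv(inner_sel, config = config, seed = seed)
    fit <- e1071::svm(t(inner_sel$values), factor(inner$labels, levels = c(0, 1)),
      type = "C-classification", kernel = "radial",
      cost = gs$best_C, gamma = gs$best_gamma, scale = TRUE
    )
    newx <- t(subset_features(table, feats)$values[, i, drop = FALSE])
    preds[i] <- as.integer(as.character(stats::predict(fit, newx)))
    fold_info[[i]] <- list(features = feats, C = gs$best_C, gamma = gs$best_gamma)
  }
  cm <- confusion_from_predictions(preds, table$labels)
  list(
    predictions = preds,
    confusion = cm,
    metrics = compute_metrics(cm),
    folds = fold_info
  )
}

#' Compare feature families through the selection-classification pipeline
#'
#' Runs LASSO feature selection, RBF-SVM grid search under LOOCV, and the
#' five performance metrics for each feature family (component loadings and
#' single-task baselines) with an identical grid and fold scheme, and
#' tabulates the results.
#'
#' @param tables Named list of [feature_table()] objects sharing participants
#'   and labels.
#' @param config An [svm_config()].
#' @param seed Recorded seed.
#' @param nested If TRUE, use [nested_svm_loocv()] (selection and tuning
#'   re-run inside every fold); default FALSE replicates the published
#'   topology (selection once on the full sample).
#' @return Object of class `family_comparison`: per-family results plus a
#'   `summary` data.frame (one row per family: selected lambda, feature
#'   count, chosen C and gamma, and the five metrics).
#' @export
compare_feature_sets <- function(tables, config = svm_config(), seed = 1L,
                                 nested = FALSE) {
  if (length(tables) == 0L) stop("no feature tables given", call. = FALSE)
  ref <- tables[[1L]]
  for (tab in tables) {
    if (!identical(tab$participant_ids, ref$participant_ids) ||
      !identical(tab$labels, ref$labels)) {
      stop("all families must share participants and labels", call. = FALSE)
    }
  }
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) t$family, character(1))
  }
  results <- lapply(tables, function(tab) {
    if (nested) {
      path_obj <- select_lambda_loocv(tab)
      nest <- nested_svm_loocv(tab, config = config, seed = seed)
      list(
        family = tab$family, path = path_obj,
        features = unique(unlist(lapply(nest$folds, `[[`, "features"))),
        svm = NULL, confusion = nest$confusion, metrics = nest$metrics,
        nested = nest
      )
    } else {
      classify_family_pooled(tab, config, seed)
    }
  })
  summary_df <- do.call(rbind, lapply(results, function(r) {
    disp <- r$metrics$display
    data.frame(
      family = r$family,
      n_features = length(r$features),
      lambda = r$path$selected_lambda,
      C = if (is.null(r$svm)) NA_real_ else r$svm$best_C,
      gamma = if (is.null(r$svm)) NA_real_ else r$svm$best_gamma,
      accuracy = disp[["accuracy"]],
      recall = disp[["recall"]],
      precision = disp[["precision"]],
      specificity = disp[["specificity"]],
      f2 = disp[["f2"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary_df) <- NULL
  structure(
    list(results = results, summary = summary_df, nested = nested,
         seed = as.integer(seed)),
    class = "family_comparison"
  )
}

#' @export
print.family_comparison <- function(x, ...) {
  cat(sprintf(
    "Feature-family comparison (%s LOOCV):\n",
    if (x$nested) "nested" else "pooled-selection"
  ))
  print(x$summary, digits = 4)
  invisible(x)
}
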