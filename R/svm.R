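# Radial-kernel soft-margin SVM classification under LOOCV, with grid search
# over cost C and kernel width gamma, pooled held-out predictions, the five
# performance metrics, and exact confusion-matrix reconstruction from
# rounded recall/specificity.

#' Grid configuration for the RBF-SVM search
#'
#' Log-equispaced grids for the misclassification cost `C` and kernel width
#' `gamma` of the radial kernel `exp(-gamma * |x_i - x_j|^2)`, both over
#' \[0.1, 10\] by default.
#'
#' @param C_range,gamma_range Length-2 ranges (positive).
#' @param resolution Number of grid values per parameter (default 20).
#' @return Object of class `svm_config` with `C_grid` and `gamma_grid`.
#' @export
svm_config <- function(C_range = c(0.1, 10), gamma_range = c(0.1, 10),
                       resolution = 20L) {
  stopifnot(
    length(C_range) == 2L, all(C_range > 0), C_range[1] <= C_range[2],
    length(gamma_range) == 2L, all(gamma_range > 0),
    gamma_range[1] <= gamma_range[2], resolution >= 1L
  )
  structure(
    list(
      C_grid = exp(seq(log(C_range[1]), log(C_range[2]),
        length.out = resolution
      )),
      gamma_grid = exp(seq(log(gamma_range[1]), log(gamma_range[2]),
        length.out = resolution
      )),
      resolution = as.integer(resolution)
    ),
    class = "svm_config"
  )
}

# Center and unit-scale feature columns once on the full sample (the
# pipeline's fixed preprocessing convention); constant columns become zero.
scale_features <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, `/`)
}

# LOOCV class predictions at one (C, gamma) on pre-scaled features; rows of
# `X` are participants.
svm_loocv_predictions <- function(X, y, C, gamma) {
  m <- nrow(X)
  yf <- factor(y, levels = c(0, 1))
  pred <- integer(m)
  for (i in seq_len(m)) {
    fit <- e1071::svm(X[-i, , drop = FALSE], yf[-i],
      type = "C-classification", kernel = "radial",
      cost = C, gamma = gamma, scale = FALSE
    )
    pred[i] <- as.integer(as.character(
      stats::predict(fit, X[i, , drop = FALSE])
    ))
  }
  pred
}

# LOOCV accuracy at one (C, gamma) via libsvm's internal n-fold
# cross-validation (each fold a single participant, so the partition is
# deterministic); identical to pooling svm_loocv_predictions().
svm_loocv_accuracy <- function(X, y, C, gamma) {
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)),
    type = "C-classification", kernel = "radial",
    cost = C, gamma = gamma, scale = FALSE, cross = nrow(X)
  )
  fit$tot.accuracy / 100
}

#' RBF-SVM grid search under leave-one-out cross-validation
#'
#' For every (C, gamma) pair on the grid, each participant is held out once,
#' the SVM is trained on the rest, and pooled held-out accuracy is recorded.
#' The returned pair maximizes LOOCV accuracy; ties break toward the
#' smallest C, then the smallest gamma (maximum regularization). The
#' procedure is deterministic; `seed` is accepted for interface uniformity
#' and recorded in the result.
#'
#' @param table A [feature_table()] (typically already reduced to the
#'   selected features), with at least 4 participants and both classes.
#' @param config An [svm_config()].
#' @param seed Integer recorded in the result (no randomness is consumed).
#' @param scale Center and unit-scale the features on the full sample before
#'   cross-validation (default TRUE).
#' @return Object of class `svm_loocv`: `best_C`, `best_gamma`,
#'   `accuracy` (LOOCV accuracy at the best pair), `predictions` (pooled
#'   held-out labels at the best pair), `labels`, and the full
#'   `accuracy_grid` (C x gamma matrix).
#' @export
svm_grid_search_loocv <- function(table, config = svm_config(), seed = 1L,
                                  scale = TRUE) {
  check_two_classes(table)
  X <- t(table$values)
  y <- table$labels
  if (nrow(X) < 4L) stop("need at least 4 participants", call. = FALSE)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  if (scale) X <- scale_features(X)
  nc <- length(config$C_grid)
  ng <- length(config$gamma_grid)
  acc <- matrix(NA_real_, nc, ng,
    dimnames = list(
      signif(config$C_grid, 4),
      signif(config$gamma_grid, 4)
    )
  )
  for (a in seq_len(nc)) {
    for (b in seq_len(ng)) {
      acc[a, b] <- svm_loocv_accuracy(X, y, config$C_grid[a], config$gamma_grid[b])
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  # ties: smallest C then smallest gamma; grids ascend, so take the
  # lexicographically first (row, then column) hit
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
  best_C <- config$C_grid[best[1L]]
  best_gamma <- config$gamma_grid[best[2L]]
  predictions <- svm_loocv_predictions(X, y, best_C, best_gamma)
  structure(
    list(
      best_C = best_C,
      best_gamma = best_gamma,
      accuracy = acc[best[1L], best[2L]],
      predictions = predictions,
      labels = y,
      accuracy_grid = acc,
      seed = as.integer(seed),
      family = table$family
    ),
    class = "svm_loocv"
  )
}

#' @export
print.svm_loocv <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM LOOCV [%s]: best C = %.3g, gamma = %.3g, accuracy = %.3f\n",
    x$family, x$best_C, x$best_gamma, x$accuracy
  ))
  invisible(x)
}

#' Confusion matrix from pooled predictions
#'
#' Standard 2x2 counts with the patient class (label 1) as positive.
#'
#' @param predictions,labels Binary (0/1) vectors of equal length.
#' @return Object of class `confusion_matrix` with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_from_predictions <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have equal length", call. = FALSE)
  }
  if (!is_binary01(predictions) || !is_binary01(labels)) {
    stop("`predictions` and `labels` must be 0/1", call. = FALSE)
  }
  confusion_matrix(
    TP = sum(predictions == 1 & labels == 1),
    FP = sum(predictions == 1 & labels == 0),
    TN = sum(predictions == 0 & labels == 0),
    FN = sum(predictions == 0 & labels == 1)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(!is.finite(counts)) || any(counts < 0) ||
    any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(
    list(
      TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN)
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "Confusion matrix: TP=%d FP=%d TN=%d FN=%d\n",
    x$TP, x$FP, x$TN, x$FN
  ))
  invisible(x)
}

#' The five classification performance metrics
#'
#' Computes accuracy, recall (sensitivity), precision (positive predictive
#' value), specificity, and the F2 score
#' `5 * precision * recall / (4 * precision + recall)` from exact
#' (unrounded) fractions. A metric whose denominator is zero is reported as
#' 0 and flagged in `undefined`. Display values are rounded to 2 decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report`: exact `accuracy`, `recall`,
#'   `precision`, `specificity`, `f2`; `display` (2-dp rounded named
#'   vector); `undefined` (names of zero-denominator metrics); and the
#'   confusion matrix.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  frac <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  accuracy <- (cm$TP + cm$TN) / total
  recall <- frac(cm$TP, cm$TP + cm$FN, "recall")
  precision <- frac(cm$TP, cm$TP + cm$FP, "precision")
  specificity <- frac(cm$TN, cm$TN + cm$FP, "specificity")
  f2 <- if (4 * precision + recall > 0) {
    5 * precision * recall / (4 * precision + recall)
  } else {
    undefined <- c(undefined, "f2")
    0
  }
  vals <- c(
    accuracy = accuracy, recall = recall, precision = precision,
    specificity = specificity, f2 = f2
  )
  structure(
    list(
      accuracy = accuracy, recall = recall, precision = precision,
      specificity = specificity, f2 = f2,
      display = round2(vals),
      undefined = undefined,
      confusion = cm
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Performance metrics (2 dp):\n")
  print(x$display)
  if (length(x$undefined) > 0) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct an integer confusion matrix from rounded metrics
#'
#' Exhaustively searches TP in 0..n_pos and TN in 0..n_neg for confusion
#' matrices whose recall and specificity round to the given 2-dp values
#' (the same rounding convention as the display metrics). With the group
#' sizes fixed, printed recall and specificity typically pin down the
#' integer matrix uniquely, turning rounded published metrics into exact
#' count targets.
#'
#' @param recall_2dp,specificity_2dp Rounded values in \[0, 1\].
#' @param n_pos,n_neg Positive and negative class sizes.
#' @return A [confusion_matrix()] when the solution is unique; otherwise a
#'   list of class `confusion_candidates` holding every candidate (empty if
#'   none match).
#' @export
#' @examples
#' reconstruct_confusion(0.79, 0.81, 19, 21) # TP = 15, TN = 17
reconstruct_confusion <- function(recall_2dp, specificity_2dp, n_pos, n_neg) {
  stopifnot(
    recall_2dp >= 0, recall_2dp <= 1,
    specificity_2dp >= 0, specificity_2dp <= 1,
    n_pos > 0, n_neg > 0
  )
  cands <- list()
  for (tp in 0:n_pos) {
    if (abs(round2(tp / n_pos) - recall_2dp) > 1e-9) next
    for (tn in 0:n_neg) {
      if (abs(round2(tn / n_neg) - specificity_2dp) > 1e-9) next
      cands[[length(cands) + 1L]] <- confusion_matrix(
        TP = tp, FP = n_neg - tn, TN = tn, FN = n_pos - tp
      )
    }
  }
  if (length(cands) == 1L) {
    return(cands[[1L]])
  }
  structure(cands, class = "confusion_candidates")
}

#' @export
print.confusion_candidates <- function(x, ...) {
  cat(sprintf("%d candidate confusion matrix(es)\n", length(x)))
  for (cm in x) print(cm)
  invisible(x)
}
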