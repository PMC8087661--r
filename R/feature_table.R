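#' Construct a cross-participant feature table
#'
#' One feature family for all participants: a features-by-participants
#' matrix (rows are ROIs, columns participants) with binary group labels
#' (patient = 1, control = 0) and a family tag naming the feature source
#' (a principal component's loadings or one task's ROI beta values).
#'
#' @param values Numeric p x m matrix.
#' @param feature_names Character length p; defaults to rownames.
#' @param labels Binary vector (0/1) of length m.
#' @param family Family tag, e.g. "PC2" or "picture".
#' @param participant_ids Optional identifiers, length m.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, feature_names = rownames(values),
                          labels, family = "features",
                          participant_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("`values` must be a finite numeric matrix", call. = FALSE)
  }
  if (is.null(feature_names) || length(feature_names) != nrow(values)) {
    stop("`feature_names` must have one entry per row", call. = FALSE)
  }
  if (length(labels) != ncol(values) || !is_binary01(labels)) {
    stop("`labels` must be 0/1 with one entry per participant", call. = FALSE)
  }
  if (is.null(participant_ids)) {
    participant_ids <- sprintf("S%03d", seq_len(ncol(values)))
  }
  dimnames(values) <- list(feature_names, participant_ids)
  structure(
    list(
      values = values,
      feature_names = as.character(feature_names),
      labels = as.integer(labels),
      family = family,
      participant_ids = as.character(participant_ids)
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table [%s]: %d features x %d participants (%d/%d)\n",
    x$family, nrow(x$values), ncol(x$values),
    sum(x$labels == 1), sum(x$labels == 0)
  ))
  invisible(x)
}

# Both classes must be present for any supervised stage.
check_two_classes <- function(table) {
  if (length(unique(table$labels)) < 2L) {
    stop("both classes must be present in the feature table", call. = FALSE)
  }
  invisible(table)
}

#' Subset a feature table to named features
#'
#' @param table A [feature_table()].
#' @param features Character vector of feature names to keep.
#' @return A [feature_table()] with the selected rows, in the given order.
#' @export
subset_features <- function(table, features) {
  idx <- match(features, table$feature_names)
  if (anyNA(idx)) stop("unknown feature name(s)", call. = FALSE)
  feature_table(table$values[idx, , drop = FALSE],
    feature_names = features, labels = table$labels,
    family = table$family, participant_ids = table$participant_ids
  )
}
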