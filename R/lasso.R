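# L1-penalized logistic feature selection over a feature table.
#
# The penalized fits come from glmnet (coordinate descent, warm starts along
# the path); this module owns the lambda-grid construction, the
# leave-one-out binomial-deviance selection harness, and the reporting of
# selected features. Features are standardized internally (glmnet default);
# coefficients are reported on the original scale.

# glmnet-convention standard deviation: denominator n, not n - 1.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Log-spaced regularization grid for LASSO logistic selection
#'
#' `lambda_max` is the smallest penalty at which every coefficient is zero:
#' for the standardized-feature binomial model with observation weight 1/m
#' this is `max_j |<x_j_std, y - mean(y)>| / m`. The grid holds 100 values,
#' equispaced on the log scale, descending from `lambda_max` to
#' `0.01 * lambda_max`.
#'
#' @param table A [feature_table()] with both classes present.
#' @param nlambda Number of grid values (default 100).
#' @param min_ratio Ratio of the smallest to the largest value (default 0.01).
#' @return Numeric vector of `nlambda` descending penalties.
#' @export
make_lambda_grid <- function(table, nlambda = 100L, min_ratio = 0.01) {
  check_two_classes(table)
  X <- t(table$values) # participants x features
  y <- table$labels
  m <- length(y)
  r <- y - mean(y)
  scores <- apply(X, 2, function(x) {
    s <- sd_pop(x)
    if (s == 0) {
      return(0)
    }
    abs(sum((x - mean(x)) / s * r)) / m
  })
  lambda_max <- max(scores)
  if (lambda_max <= 0) {
    stop("cannot construct a grid: all features are constant", call. = FALSE)
  }
  exp(seq(log(lambda_max), log(min_ratio * lambda_max), length.out = nlambda))
}

#' Coefficient path of the L1-penalized logistic model
#'
#' Fits the binomial LASSO at every grid penalty (warm-started along the
#' path) and returns intercepts and original-scale coefficients.
#'
#' @param table A [feature_table()].
#' @param lambdas Descending penalty grid, e.g. from [make_lambda_grid()].
#' @param standardize Standardize features internally (default TRUE).
#' @param thresh Convergence threshold of the coordinate-descent solver.
#' @return List with `lambdas`, `intercepts` (length-nlambda vector) and
#'   `coefficients` (features x nlambda matrix, original scale).
#' @export
lasso_logistic_path <- function(table, lambdas, standardize = TRUE,
                                thresh = 1e-10) {
  check_two_classes(table)
  X <- t(table$values)
  y <- table$labels
  fit <- glmnet_quiet(glmnet::glmnet(X, y,
    family = "binomial", lambda = lambdas,
    standardize = standardize, thresh = thresh, maxit = 1e5
  ))
  if (length(fit$lambda) != length(lambdas)) {
    stop(sprintf(
      "path fit did not converge for all penalties (stopped at index %d)",
      length(fit$lambda)
    ), call. = FALSE)
  }
  beta <- as.matrix(fit$beta)
  rownames(beta) <- table$feature_names
  list(
    lambdas = lambdas,
    intercepts = as.numeric(fit$a0),
    coefficients = beta
  )
}

# Held-out binomial deviance contribution of one observation, with
# probability clipping to keep the deviance finite.
heldout_deviance <- function(y, p, clip = 1e-8) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

#' Select the penalty by leave-one-out binomial deviance
#'
#' For each participant in turn, the path is refit on the remaining m - 1
#' and the held-out binomial deviance `-2[y log p + (1 - y) log(1 - p)]` is
#' accumulated at every grid penalty; the selected penalty minimizes the
#' total, with ties broken toward the larger (sparser) penalty. Held-out
#' probabilities are clipped at 1e-8.
#'
#' @param table A [feature_table()] with at least 3 participants.
#' @param lambdas Penalty grid; defaults to [make_lambda_grid()] on `table`.
#' @param standardize Standardize features internally (default TRUE).
#' @return Object of class `lasso_path`: the grid, per-penalty total LOOCV
#'   deviances, `selected_lambda`, its index, full-data `coefficients` and
#'   `intercept` at the selected penalty, and `selected_features` (names
#'   with nonzero coefficient, descending by magnitude).
#' @export
select_lambda_loocv <- function(table, lambdas = NULL, standardize = TRUE) {
  check_two_classes(table)
  m <- ncol(table$values)
  if (m < 3L) stop("need at least 3 participants for LOOCV", call. = FALSE)
  if (is.null(lambdas)) lambdas <- make_lambda_grid(table)
  X <- t(table$values)
  y <- table$labels
  dev <- numeric(length(lambdas))
  for (i in seq_len(m)) {
    fit <- glmnet_quiet(glmnet::glmnet(X[-i, , drop = FALSE], y[-i],
      family = "binomial", lambda = lambdas,
      standardize = standardize, thresh = 1e-10, maxit = 1e5
    ))
    p_hat <- as.numeric(stats::predict(fit,
      newx = X[i, , drop = FALSE],
      s = lambdas, type = "response"
    ))
    dev <- dev + heldout_deviance(y[i], p_hat)
  }
  # ties toward larger lambda: grid is descending, so take the first minimum
  sel <- which(dev <= min(dev) + 1e-12)[1L]
  path <- lasso_logistic_path(table, lambdas, standardize = standardize)
  coefs <- path$coefficients[, sel]
  nz <- which(coefs != 0)
  ord <- nz[order(abs(coefs[nz]), decreasing = TRUE)]
  structure(
    list(
      lambdas = lambdas,
      deviances = dev,
      selected_lambda = lambdas[sel],
      selected_index = sel,
      intercept = path$intercepts[sel],
      coefficients = coefs,
      selected_features = table$feature_names[ord],
      family = table$family,
      n = m
    ),
    class = "lasso_path"
  )
}

#' Features selected at the minimum-deviance penalty
#'
#' @param path A `lasso_path` from [select_lambda_loocv()].
#' @return Character vector of nonzero-coefficient feature names, in
#'   descending order of coefficient magnitude (empty if the selected model
#'   is the null model).
#' @export
selected_features <- function(path) {
  stopifnot(inherits(path, "lasso_path"))
  path$selected_features
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "LASSO LOOCV path [%s]: %d penalties, m = %d\n", x$family,
    length(x$lambdas), x$n
  ))
  cat(sprintf(
    "  selected lambda = %.4g (min total deviance %.3f), %d feature(s) selected\n",
    x$selected_lambda, min(x$deviances), length(x$selected_features)
  ))
  if (length(x$selected_features) > 0) {
    cat("  ", paste(x$selected_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.lasso_path <- function(x, ...) {
  graphics::plot(log(x$lambdas), x$deviances,
    type = "b", pch = 20,
    xlab = expression(log(lambda)),
    ylab = "total LOOCV binomial deviance",
    main = sprintf("Penalty selection [%s]", x$family), ...
  )
  graphics::abline(v = log(x$selected_lambda), lty = 2, col = 2)
  invisible(x)
}
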