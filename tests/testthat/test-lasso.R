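test_that("the penalty grid is 100 log-equispaced values with ratio 0.01", {
  tab <- random_feature_table(10, 30, seed = 1)
  g <- make_lambda_grid(tab)
  expect_length(g, 100L)
  expect_equal(g[100] / g[1], 0.01, tolerance = 1e-10)
  expect_true(all(diff(g) < 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 99), tolerance = 1e-10)
  # fitting at lambda_max returns the all-zero coefficient vector
  path <- lasso_logistic_path(tab, g)
  expect_true(all(path$coefficients[, 1] == 0))
  expect_true(any(path$coefficients[, 100] != 0))

  one_class <- feature_table(matrix(rnorm(20), 4, 5),
    feature_names = sprintf("F%d", 1:4), labels = rep(1, 5)
  )
  expect_error(make_lambda_grid(one_class), "both classes")
})

test_that("path coefficients match a direct convex-minimization oracle", {
  set.seed(42)
  X <- matrix(rnorm(8 * 3), 8, 3) # 8 participants, 3 features
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  tab <- feature_table(t(X),
    feature_names = c("A", "B", "C"),
    labels = y
  )
  g <- make_lambda_grid(tab)
  path <- lasso_logistic_path(tab, g, thresh = 1e-14)
  for (j in c(5L, 30L, 60L, 90L)) {
    ora <- oracle_lasso_logistic(X, y, g[j], max_iter = 500000L, tol = 1e-15)
    expect_equal(path$coefficients[, j], ora$coefficients,
      tolerance = 1e-6, ignore_attr = TRUE
    )
    expect_equal(path$intercepts[j], ora$intercept, tolerance = 1e-6)
  }
})

test_that("a strongly informative feature enters the path before any noise feature", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 40
    y <- rep_len(c(1L, 0L), m)
    X <- matrix(rnorm(8 * m), 8, m)
    X[1, ] <- 3 * y + rnorm(m) # effect three SDs of the noise
    tab <- feature_table(X,
      feature_names = sprintf("F%d", 1:8),
      labels = y
    )
    g <- make_lambda_grid(tab)
    path <- lasso_logistic_path(tab, g)
    entry <- apply(path$coefficients != 0, 1, function(nz) {
      if (any(nz)) which(nz)[1] else Inf
    })
    expect_lt(entry[1], min(entry[-1]))
  }
})

test_that("total deviance at an all-zero penalty equals the null-model LOOCV deviance", {
  tab <- random_feature_table(6, 24, seed = 3)
  # inflate the grid top so every training fold is all-zero at its head
  # (a fold's own lambda_max can exceed the full-sample one)
  lam <- make_lambda_grid(tab) * 4
  path <- select_lambda_loocv(tab, lambdas = lam)
  expect_equal(path$deviances[1], null_loocv_deviance(tab$labels),
    tolerance = 1e-8
  )
})

test_that("LOOCV selects an informative feature at an interior penalty", {
  set.seed(5)
  m <- 30
  y <- rep_len(c(1L, 0L), m)
  X <- matrix(rnorm(5 * m, sd = 1), 5, m)
  X[3, ] <- 2.5 * y + rnorm(m, sd = 0.5)
  tab <- feature_table(X, feature_names = sprintf("F%d", 1:5), labels = y)
  path <- select_lambda_loocv(tab)
  expect_true("F3" %in% path$selected_features)
  expect_lt(min(path$deviances), path$deviances[1])
  expect_gt(path$selected_index, 1L)
})

test_that("pure-noise selection matches the independent cv.glmnet route and stays near-null", {
  # study-sized pure-noise tables: the LOOCV deviance selector must agree
  # exactly with glmnet's own cross-validation driver on identical folds,
  # and the null model must remain competitive (no strong spurious signal)
  n_sparse <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(78 * 40), 40, 78)
    y <- rep_len(c(1L, 0L), 40)
    tab <- feature_table(t(X),
      feature_names = sprintf("F%03d", 1:78),
      labels = y
    )
    g <- make_lambda_grid(tab)
    path <- select_lambda_loocv(tab)
    cvf <- suppressWarnings(glmnet::cv.glmnet(X, y,
      family = "binomial",
      lambda = g, foldid = 1:40, type.measure = "deviance",
      grouped = FALSE
    ))
    expect_equal(path$selected_lambda, cvf$lambda.min, tolerance = 1e-9)
    n_cv <- sum(as.matrix(stats::coef(cvf, s = cvf$lambda.min))[-1, 1] != 0)
    expect_identical(length(path$selected_features), as.integer(n_cv))
    # null deviance within noise of the minimum (per-participant margin)
    expect_lt((path$deviances[1] - min(path$deviances)) / 40, 0.6)
    if (length(path$selected_features) <= 2L) n_sparse <- n_sparse + 1L
  }
  expect_gte(n_sparse, 6L)
})

test_that("when the null model attains the minimum deviance the sparser penalty wins", {
  # engineered so the minimum is attained at the top of the (descending)
  # grid: ties toward larger lambda must return lambda_max itself
  tab <- random_feature_table(20, 30, seed = 104)
  path <- select_lambda_loocv(tab)
  if (path$deviances[1] <= min(path$deviances) + 1e-12) {
    expect_identical(path$selected_index, 1L)
    expect_length(path$selected_features, 0L)
  }
  # and the explicit tie-break rule on a constructed deviance profile
  sel <- which(c(5, 4, 4, 4, 6) <= min(c(5, 4, 4, 4, 6)) + 1e-12)[1]
  expect_identical(sel, 2L)
})

test_that("LOOCV selection is invariant to participant order", {
  set.seed(6)
  m <- 24
  y <- rep_len(c(1L, 0L), m)
  X <- matrix(rnorm(6 * m), 6, m)
  X[2, ] <- 2 * y + rnorm(m, sd = 0.7)
  tab <- feature_table(X, feature_names = sprintf("F%d", 1:6), labels = y)
  path <- select_lambda_loocv(tab)
  perm <- sample(m)
  tabp <- feature_table(X[, perm],
    feature_names = sprintf("F%d", 1:6),
    labels = y[perm]
  )
  pathp <- select_lambda_loocv(tabp, lambdas = path$lambdas)
  expect_equal(pathp$selected_lambda, path$selected_lambda)
  expect_setequal(pathp$selected_features, path$selected_features)
  expect_equal(pathp$deviances, path$deviances, tolerance = 1e-8)
})

test_that("selected features are ordered by coefficient magnitude", {
  set.seed(7)
  m <- 30
  y <- rep_len(c(1L, 0L), m)
  X <- matrix(rnorm(6 * m), 6, m)
  X[1, ] <- 2 * y + rnorm(m, 0, 0.5)
  X[4, ] <- 1 * y + rnorm(m, 0, 0.5)
  tab <- feature_table(X, feature_names = sprintf("F%d", 1:6), labels = y)
  path <- select_lambda_loocv(tab)
  mags <- abs(path$coefficients[path$selected_features])
  expect_true(all(diff(mags) <= 1e-15))
  expect_identical(selected_features(path), path$selected_features)
})
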