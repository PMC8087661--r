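# orthonormal columns orthogonal to the ones vector, for closed-form cases
centered_orthobasis <- function(p, k, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(p * k), p, k)
  Z <- sweep(Z, 2, colMeans(Z))
  qr.Q(qr(Z))
}

test_that("rank-1 matrices put all variance on the first component", {
  set.seed(1)
  base <- rexp(10)
  X <- cbind(base + 1, base + 2, base + 5) # columns equal after centering
  fit <- subject_pca(X)
  expect_equal(fit$explained_proportions, c(1, 0, 0), tolerance = 1e-12)
})

test_that("orthogonal centered columns give closed-form proportions", {
  Q <- centered_orthobasis(8, 3, seed = 2)
  X <- Q %*% diag(c(3, 2, 1))
  fit <- subject_pca(X + 10) # constant shift is removed by centering
  expect_equal(fit$explained_proportions, c(9, 4, 1) / 14, tolerance = 1e-12)
  # singular values of the centered matrix scaled by 1/sqrt(n - 1)
  expect_equal(fit$singular_values, c(3, 2, 1) / sqrt(2), tolerance = 1e-10)
})

test_that("subject_pca agrees with the covariance eigendecomposition oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rexp(78 * 3, rate = 4), 78, 3)
    fit <- subject_pca(X)
    ora <- oracle_pca(X)
    expect_equal(fit$explained_proportions, ora$proportions,
      tolerance = 1e-10
    )
    expect_equal(abs(fit$components), abs(ora$components),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    # structural invariants
    expect_equal(crossprod(fit$components), diag(3), tolerance = 1e-8,
      ignore_attr = TRUE
    )
    expect_equal(sum(fit$explained_proportions), 1, tolerance = 1e-10)
    expect_true(all(diff(fit$explained_proportions) <= 1e-12))
    expect_true(all(fit$singular_values >= 0))
  }
})

test_that("the decomposition reconstructs the centered scaled matrix", {
  set.seed(9)
  X <- matrix(rexp(30), 10, 3)
  fit <- subject_pca(X)
  Xs <- sweep(X, 2, colMeans(X)) / sqrt(2)
  expect_equal(fit$components %*% t(fit$scores), Xs,
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("explained proportions are invariant to positive rescaling", {
  set.seed(10)
  X <- matrix(rexp(30), 10, 3)
  f1 <- subject_pca(X)
  f2 <- subject_pca(3.7 * X)
  expect_equal(f1$explained_proportions, f2$explained_proportions,
    tolerance = 1e-12
  )
})

test_that("degenerate zero-variance matrices are rejected", {
  expect_error(subject_pca(matrix(2, 10, 3)), "degenerate")
  expect_error(subject_pca(matrix(rnorm(6), 2, 3)), "more rows")
})

test_that("sign alignment flips lone dissenters and is idempotent", {
  # similar components across subjects: perturbations of a common matrix
  set.seed(11)
  X0 <- matrix(rexp(30), 10, 3)
  mats <- lapply(1:5, function(i) X0 + matrix(rnorm(30, sd = 0.05), 10, 3))
  pcas <- lapply(mats, subject_pca)
  # force one subject's component 2 to the opposite orientation
  pcas[[3]]$components[, 2] <- -pcas[[3]]$components[, 2]
  pcas[[3]]$scores[, 2] <- -pcas[[3]]$scores[, 2]
  before <- lapply(pcas, function(f) f$components[, 2])
  aligned <- align_component_signs(pcas, 2)
  after <- lapply(aligned, function(f) f$components[, 2])
  # magnitudes never change
  for (j in 1:5) expect_equal(abs(after[[j]]), abs(before[[j]]))
  # the dissenter is flipped back: all pairwise inner products positive
  for (a in 1:4) {
    for (b in (a + 1):5) {
      expect_gt(sum(after[[a]] * after[[b]]), 0)
    }
  }
  # untouched subjects keep their orientation
  for (j in c(1, 2, 4, 5)) expect_equal(after[[j]], before[[j]])
  expect_equal(after[[3]], -before[[3]])
  # idempotence
  twice <- align_component_signs(aligned, 2)
  expect_equal(
    lapply(twice, function(f) f$components),
    lapply(aligned, function(f) f$components)
  )
  # the aligned scores still reconstruct each centered scaled matrix
  for (j in 1:5) {
    Xs <- sweep(mats[[j]], 2, colMeans(mats[[j]])) / sqrt(2)
    expect_equal(aligned[[j]]$components %*% t(aligned[[j]]$scores), Xs,
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
})

test_that("feature matrices stack aligned loadings by participant", {
  ds <- generate_dataset(synthetic_config(seed = 5))
  pcas <- align_component_signs(lapply(ds$beta_matrices, subject_pca), 2)
  tab <- build_feature_matrix(pcas, 2, ds$labels)
  expect_identical(dim(tab$values), c(78L, 40L))
  expect_identical(tab$family, "PC2")
  expect_equal(tab$values[, 17], pcas[[17]]$components[, 2],
    ignore_attr = TRUE
  )

  # single participant
  tab1 <- build_feature_matrix(pcas[1], 2, ds$labels[1])
  expect_identical(dim(tab1$values), c(78L, 1L))

  # permuting participants permutes columns and labels consistently
  set.seed(2)
  perm <- sample(40)
  tabp <- build_feature_matrix(pcas[perm], 2, ds$labels[perm])
  expect_equal(tabp$values, tab$values[, perm], ignore_attr = TRUE)
  expect_identical(tabp$labels, tab$labels[perm])

  # mismatched ROI dimension errors
  small <- subject_pca(matrix(rexp(15), 5, 3))
  expect_error(
    build_feature_matrix(c(pcas[1:2], list(small)), 2, c(1, 0, 1)),
    "ROI dimension"
  )
})

test_that("single-task features project the source matrices", {
  ds <- generate_dataset(synthetic_config(n_pos = 3, n_neg = 3, n_rois = 10, seed = 2))
  tab <- build_single_task_features(ds$beta_matrices, "sound", ds$labels)
  expect_identical(dim(tab$values), c(10L, 6L))
  for (j in 1:6) {
    expect_equal(tab$values[, j], ds$beta_matrices[[j]]$values[, 2],
      ignore_attr = TRUE
    )
  }
  expect_error(
    build_single_task_features(ds$beta_matrices, "rest", ds$labels),
    "unknown task"
  )
})

test_that("zero-noise group means equal the mixed group patterns", {
  cfg <- synthetic_config(
    n_pos = 4, n_neg = 4, n_rois = 12,
    noise_sd = 0, jitter_sd = 0, seed = 6
  )
  ds <- generate_dataset(cfg)
  S <- diag(cfg$singular_values)
  V <- cfg$task_mixing
  for (g in c(1L, 0L)) {
    U <- if (g == 1L) cfg$group_loading_patterns$pos else cfg$group_loading_patterns$neg
    expected <- U %*% S %*% t(V)
    expected <- expected - min(expected) + cfg$positivity_offset
    for (task_j in 1:3) {
      tab <- build_single_task_features(
        ds$beta_matrices, mt_tasks()[task_j], ds$labels
      )
      gm <- rowMeans(tab$values[, tab$labels == g, drop = FALSE])
      expect_equal(gm, expected[, task_j],
        tolerance = 1e-10,
        ignore_attr = TRUE
      )
    }
  }
})

test_that("explained-variance summaries follow the group statistics", {
  # zero-noise: every subject in a group identical -> SD 0, means = shares
  cfg0 <- synthetic_config(
    n_pos = 3, n_neg = 4, n_rois = 10,
    noise_sd = 0, jitter_sd = 0, seed = 7
  )
  ds0 <- generate_dataset(cfg0)
  pcas0 <- lapply(ds0$beta_matrices, subject_pca)
  summ0 <- summarize_explained_variance(pcas0, ds0$labels)
  shares <- 100 * cfg0$singular_values^2 / sum(cfg0$singular_values^2)
  for (g in c("patient", "control")) {
    rows <- summ0[summ0$group == g, ]
    expect_equal(rows$mean, shares, tolerance = 1e-8)
    expect_equal(rows$sd, rep(0, 3), tolerance = 1e-8)
    expect_equal(sum(rows$mean), 100, tolerance = 1e-8)
  }

  # jittered data: SEM = SD / sqrt(n) against direct computation
  ds <- generate_dataset(synthetic_config(n_pos = 5, n_neg = 6, n_rois = 15, seed = 8))
  pcas <- lapply(ds$beta_matrices, subject_pca)
  summ <- summarize_explained_variance(pcas, ds$labels)
  expect_equal(summ$sem, summ$sd / sqrt(summ$n), tolerance = 1e-10)
  props <- t(vapply(pcas, function(f) f$explained_proportions, numeric(3)))
  pat <- which(ds$labels == 1)
  expect_equal(
    summ$mean[summ$group == "patient"],
    100 * colMeans(props[pat, ]),
    tolerance = 1e-10
  )
  expect_equal(
    tapply(summ$mean, summ$group, sum),
    c(control = 100, patient = 100),
    tolerance = 1e-8, ignore_attr = TRUE
  )

  expect_error(
    summarize_explained_variance(pcas[1:3], c(1, 0, 0)),
    "at least 2"
  )
})

test_that("voxel PCA recovers planted anticorrelated spatial patterns", {
  dims <- c(4, 4, 4)
  region_a <- array(FALSE, dims)
  region_a[1:2, , ] <- TRUE
  region_b <- !region_a
  pattern <- array(0, dims)
  pattern[region_a] <- 1
  pattern[region_b] <- -1
  set.seed(3)
  v1 <- pattern + array(rnorm(64, sd = 0.01), dims)
  v2 <- -pattern + array(rnorm(64, sd = 0.01), dims)
  v3 <- array(rnorm(64, sd = 0.01), dims)
  vp <- voxel_pca(list(picture = v1, sound = v2, stroop = v3))
  map1 <- vp$maps$PC1
  expect_true(all(sign(map1[region_a]) == sign(map1[region_a][1])))
  expect_true(all(sign(map1[region_b]) == -sign(map1[region_a][1])))
  expect_gt(vp$explained_proportions[1], 0.9)

  # identical volumes: first component explains everything
  same <- array(rexp(64), dims)
  vp2 <- voxel_pca(list(a = same + 1, b = same + 3))
  expect_equal(vp2$explained_proportions[1], 1, tolerance = 1e-10)

  # masked-out voxels are absent from loadings and NA in maps
  mask <- array(TRUE, dims)
  mask[4, 4, 4] <- FALSE
  vp3 <- voxel_pca(list(picture = v1, sound = v2, stroop = v3), mask)
  expect_identical(nrow(vp3$loadings), 63L)
  expect_true(is.na(vp3$maps$PC1[4, 4, 4]))

  expect_error(voxel_pca(list(only = v1)), "at least 2")
})
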