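test_that("generated datasets have the configured dimensions, labels and positivity", {
  ds <- generate_dataset(synthetic_config(seed = 4))
  expect_length(ds$beta_matrices, 40L)
  expect_identical(sum(ds$labels == 1), 19L)
  expect_identical(sum(ds$labels == 0), 21L)
  for (m in ds$beta_matrices) {
    expect_identical(dim(m$values), c(78L, 3L))
    expect_true(all(is.finite(m$values)))
    expect_true(all(m$values > 0))
  }
  expect_identical(ds$beta_matrices[[1]]$roi_names, retained_roi_names())
})

test_that("equal seeds reproduce identical datasets and different seeds differ", {
  small <- function(seed) {
    generate_dataset(synthetic_config(
      n_pos = 4, n_neg = 4, n_rois = 12,
      seed = seed
    ))
  }
  a <- small(7)
  b <- small(7)
  c <- small(8)
  va <- vapply(a$beta_matrices, function(m) m$values, a$beta_matrices[[1]]$values)
  vb <- vapply(b$beta_matrices, function(m) m$values, b$beta_matrices[[1]]$values)
  vc <- vapply(c$beta_matrices, function(m) m$values, c$beta_matrices[[1]]$values)
  expect_identical(va, vb)
  expect_false(identical(va, vc))
})

test_that("zero-noise, zero-jitter matrices are exact rank-3 group structures", {
  cfg <- synthetic_config(noise_sd = 0, jitter_sd = 0, seed = 12)
  ds <- generate_dataset(cfg)
  shares <- cfg$singular_values^2 / sum(cfg$singular_values^2)
  for (i in c(1L, 40L)) { # one patient, one control
    fit <- subject_pca(ds$beta_matrices[[i]])
    expect_equal(fit$explained_proportions, shares, tolerance = 1e-10)
    truth <- if (ds$labels[i] == 1) {
      cfg$group_loading_patterns$pos
    } else {
      cfg$group_loading_patterns$neg
    }
    for (k in 1:3) {
      err <- min(
        max(abs(fit$components[, k] - truth[, k])),
        max(abs(fit$components[, k] + truth[, k]))
      )
      expect_lt(err, 1e-8)
    }
  }
})

test_that("group component-2 differences concentrate on the effect ROIs", {
  for (seed in 1:20) {
    cfg <- synthetic_config(seed = seed)
    d2 <- abs(cfg$group_loading_patterns$pos[, 2] -
      cfg$group_loading_patterns$neg[, 2])
    eff <- cfg$effect_rois
    expect_gt(mean(d2[eff]), mean(d2[-eff]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_pos = 0), "n_pos")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_config(n_rois = 2, n_tasks = 3), "n_rois")
  expect_error(synthetic_config(effect_rois = c(1, 99)), "effect_rois")
  bad <- list(
    pos = matrix(1, 78, 3),
    neg = matrix(1, 78, 3)
  )
  expect_error(
    synthetic_config(group_loading_patterns = bad),
    "orthogonal"
  )
})

test_that("voxel volumes realize the requested ROI means under the threshold rule", {
  cfg <- synthetic_config(
    n_pos = 2, n_neg = 2, n_rois = 8, seed = 3,
    voxel_mode = TRUE, voxels_per_roi = 5
  )
  ds <- generate_dataset(cfg)
  beta <- ds$beta_matrices[[1]]
  vols <- generate_volumes(cfg, beta)
  ext <- extract_roibvals(vols$volumes, vols$atlas,
    participant_id = "S001"
  )
  expect_equal(ext$values, beta$values, tolerance = 1e-10)
  expect_false(any(ext$coverage))
})

test_that("excluded atlas regions come back uncovered from planted volumes", {
  cfg <- synthetic_config(
    n_pos = 2, n_neg = 2, seed = 3,
    voxel_mode = TRUE, voxels_per_roi = 5
  )
  ds <- generate_dataset(cfg)
  vols <- generate_volumes(cfg, ds$beta_matrices[[1]])
  full <- extract_roibvals(vols$volumes, vols$atlas,
    apply_exclusions = FALSE
  )
  excl_rows <- full$roi_names %in% aal90_excluded()
  expect_true(all(full$coverage[excl_rows, ]))
  expect_true(all(full$values[excl_rows, ] == 0))
  expect_false(any(full$coverage[!excl_rows, ]))
})

test_that("voxel mode guards its preconditions", {
  cfg <- synthetic_config(n_pos = 2, n_neg = 2, n_rois = 8, seed = 1)
  ds <- generate_dataset(cfg)
  expect_error(generate_volumes(cfg, ds$beta_matrices[[1]]), "voxel mode")
  cfg2 <- synthetic_config(
    n_pos = 2, n_neg = 2, n_rois = 8, seed = 1,
    voxel_mode = TRUE, voxels_per_roi = 2
  )
  expect_error(
    generate_volumes(cfg2, ds$beta_matrices[[1]]),
    "voxels_per_roi"
  )
})
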