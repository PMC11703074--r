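test_that("sphere neighborhoods match lattice counts", {
  mask <- array(TRUE, c(9, 9, 9))
  nb <- sphere_neighborhoods(mask, voxel_size = 3, radius_mm = 9)
  ctr <- as.character(5 + 4 * 9 + 4 * 81)
  # brute-force lattice count of integer offsets with ||v|| <= 3
  off <- expand.grid(-3:3, -3:3, -3:3)
  expect_equal(length(nb[[ctr]]), sum(sqrt(rowSums(off^2)) <= 3))  # 123
  expect_equal(length(nb[[ctr]]), 123L)
  nb1 <- sphere_neighborhoods(mask, voxel_size = 3, radius_mm = 3)
  expect_equal(length(nb1[[ctr]]), 7L)   # center + 6 face neighbors
  # corner sphere is clipped
  expect_lt(length(nb[["1"]]), 123L)
  expect_error(sphere_neighborhoods(array(FALSE, c(3, 3, 3))),
               class = "invalid_mask_error")
  expect_error(sphere_neighborhoods(mask, voxel_size = 3, radius_mm = 1),
               class = "invalid_parameter_error")
})

test_that("searchlight map is equivariant to a spatial permutation", {
  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 2)
  bv <- generate_beta_volumes(tt, grid_shape = c(8, 8, 8), voxel_size = 3,
                              roi_center = c(3, 4, 5), roi_radius = 4,
                              snr = 2, seed = 2)
  sm <- searchlight_circularity(bv, radius_mm = 6)
  # transposing the volume axes and recomputing permutes the map identically
  bvt <- bv
  bvt$data <- aperm(bv$data, c(2, 1, 3, 4))
  bvt$mask <- aperm(bv$mask, c(2, 1, 3))
  smt <- searchlight_circularity(bvt, radius_mm = 6)
  expect_equal(smt$values, aperm(sm$values, c(2, 1, 3)), tolerance = 1e-12)
})

test_that("face adjacency separates diagonal-only clusters", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE       # touch only at an edge
  lab <- geomstate:::label_components_3d(m)
  expect_equal(max(lab), 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 1, 1] <- TRUE     # share a face
  expect_equal(max(geomstate:::label_components_3d(m2)), 1L)
  # no wrap-around at array boundaries
  m3 <- array(FALSE, c(4, 4, 4))
  m3[4, 1, 1] <- TRUE; m3[1, 2, 1] <- TRUE
  expect_equal(max(geomstate:::label_components_3d(m3)), 2L)
})

test_that("group correction recovers the planted ROI and only it", {
  n_s <- 4
  subj <- lapply(1:n_s, function(s) {
    tt <- generate_design(design_spec(reps_per_cell = 1), seed = 100 + s)
    generate_beta_volumes(tt, grid_shape = c(10, 10, 10), voxel_size = 3,
                          roi_center = c(5, 5, 5), roi_radius = 6,
                          snr = 3, seed = 100 + s)
  })
  spheres <- sphere_neighborhoods(subj[[1]]$mask, 3, 6)
  tmaps <- lapply(subj, searchlight_circularity, spheres = spheres)
  pmaps <- lapply(seq_len(n_s), function(s)
    searchlight_permuted_maps(subj[[s]], spheres = spheres, n_shuffles = 15,
                              seed = 200 + s))
  gc <- group_cluster_correction(tmaps, pmaps, n_bootstrap = 200,
                                 voxel_alpha = 0.01, seed = 5)
  expect_equal(nrow(gc$clusters), 1L)
  expect_lt(max(abs(c(gc$clusters$cx, gc$clusters$cy, gc$clusters$cz) - 5)), 1.5)

  # null cohort: no planted signal, no significant clusters
  subj0 <- lapply(1:n_s, function(s) {
    tt <- generate_design(design_spec(reps_per_cell = 1), seed = 300 + s)
    generate_beta_volumes(tt, grid_shape = c(10, 10, 10), voxel_size = 3,
                          roi_center = c(5, 5, 5), roi_radius = 6,
                          snr = 0, seed = 300 + s)
  })
  tmaps0 <- lapply(subj0, searchlight_circularity, spheres = spheres)
  pmaps0 <- lapply(seq_len(n_s), function(s)
    searchlight_permuted_maps(subj0[[s]], spheres = spheres, n_shuffles = 15,
                              seed = 400 + s))
  gc0 <- group_cluster_correction(tmaps0, pmaps0, n_bootstrap = 200,
                                  voxel_alpha = 0.01, seed = 6)
  expect_equal(nrow(gc0$clusters), 0L)
})

test_that("ROI robustness separates planted from noise regions", {
  tt <- generate_design(design_spec(reps_per_cell = 2), seed = 7)
  bv <- generate_beta_volumes(tt, grid_shape = c(8, 8, 8), voxel_size = 3,
                              roi_radius = 5, snr = 3, seed = 7)
  r1 <- roi_robustness(bv, bv$roi_voxels, n_boot = 20, n_null = 60, seed = 1)
  expect_lt(r1$p, 0.05)
  expect_gt(r1$circularity, 0.5)
  # a noise region far from the ROI
  far <- which(array(seq_len(8^3), c(8, 8, 8)) > 0)[1:20]
  far <- setdiff(far, bv$roi_voxels)[1:15]
  r0 <- roi_robustness(bv, far, n_boot = 5, n_null = 60, seed = 2)
  expect_gt(r0$p, 0.05)
  expect_error(roi_robustness(bv, bv$roi_voxels[1:2]),
               class = "invalid_roi_error")
})

test_that("beta-series FC matches a brute-force correlation loop", {
  tt <- generate_design(design_spec(reps_per_cell = 2), seed = 8)
  bv <- generate_beta_volumes(tt, grid_shape = c(8, 8, 8), voxel_size = 3,
                              roi_radius = 5, snr = 1, seed = 8)
  rois <- list(a = 1:10, b = 101:110, c = 201:210)
  fc <- beta_series_fc(bv, rois)
  expect_equal(dim(fc), c(3L, 3L))
  expect_equal(diag(fc), c(a = 1, b = 1, c = 1))
  expect_equal(fc, t(fc))
  flat <- matrix(bv$data, 8^3, dim(bv$data)[4])
  for (i in 1:2) for (j in (i + 1):3) {
    si <- colMeans(flat[rois[[i]], ]); sj <- colMeans(flat[rois[[j]], ])
    expect_equal(fc[i, j], cor(si, sj), tolerance = 1e-12)
  }
  # independent noise ROIs stay weakly correlated at 72 trials
  expect_lt(max(abs(fc[upper.tri(fc)])), 0.5)
  expect_error(beta_series_fc(bv, rois["a"]), class = "invalid_parameter_error")
})

test_that("FC-behavior tests recover a planted association", {
  set.seed(9)
  n <- 12
  strength <- runif(n)
  fc_list <- lapply(seq_len(n), function(s) {
    m <- matrix(0.1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    m[1, 2] <- m[2, 1] <- strength[s] + rnorm(1, 0, 0.02)
    diag(m) <- 1
    m
  })
  score <- strength * 2 + rnorm(n, 0, 0.05)
  fam <- data.frame(roi1 = "a", roi2 = "b")
  out <- fc_brain_behavior(fc_list, score, fam)
  expect_gt(out$rho, 0.7)
  expect_lt(out$p, 0.05)
  expect_gt(out$bf10, 3)
  expect_error(fc_brain_behavior(fc_list[1:3], score[1:3], fam),
               class = "insufficient_subjects_error")
})

test_that("JZS correlation Bayes factor matches an independent quadrature", {
  # oracle: trapezoid rule on a dense grid after u = log(g) substitution
  jzs_oracle <- function(r, n) {
    u <- seq(-12, 12, length.out = 8001)
    g <- exp(u)
    f <- (1 + g)^((n - 2) / 2) * (1 + (1 - r^2) * g)^(-(n - 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)) * g  # du jacobian
    sum((f[-1] + f[-length(f)]) / 2 * diff(u))
  }
  for (r in c(0, 0.3, 0.7)) {
    expect_equal(jzs_correlation_bf(r, 20), jzs_oracle(r, 20),
                 tolerance = 1e-3)
  }
  expect_lt(jzs_correlation_bf(0, 20), 1)
  expect_gt(jzs_correlation_bf(0.8, 20), 10)
})
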