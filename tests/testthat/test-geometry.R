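test_that("circularity matches analytic shapes", {
  th <- 2 * pi * (0:359) / 360
  circle <- circularity(cbind(cos(th), sin(th)))
  expect_equal(round(circle$C, 3), 1)

  sq <- circularity(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$C, pi / 4, tolerance = 1e-12)
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)

  rect <- circularity(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_equal(rect$C, 2 * pi / 9, tolerance = 1e-12)  # A=2, P=6

  line <- circularity(cbind(0:3, rep(0, 4)))
  expect_equal(line$C, 0)

  point <- circularity(matrix(1, 3, 2))  # zero perimeter -> degenerate rule
  expect_equal(point$C, 0)

  expect_error(circularity(matrix(0, 2, 2)), class = "invalid_polygon_error")
})

test_that("circularity equals the brute-force shoelace oracle", {
  set.seed(11)
  for (i in 1:200) {
    v <- random_simple_polygon(sample(3:12, 1))
    o <- shoelace_oracle(v)
    got <- circularity(v)
    expect_equal(got$C, o$C, tolerance = 1e-12)
    expect_equal(got$area, o$area, tolerance = 1e-12)
    expect_equal(got$perimeter, o$perimeter, tolerance = 1e-12)
  }
})

test_that("circularity is invariant under rigid transforms and scaling", {
  set.seed(21)
  v0 <- random_simple_polygon(6)
  c0 <- circularity(v0)$C
  for (i in 1:50) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    if (runif(1) < 0.5) R <- R %*% diag(c(1, -1))   # reflection
    s <- exp(runif(1, -2, 2))
    shift <- rnorm(2, 0, 10)
    v <- sweep(s * v0 %*% R, 2, shift, "+")
    expect_equal(circularity(v)$C, c0, tolerance = 1e-9)
  }
})

test_that("no random simple quadrilateral beats the square", {
  set.seed(31)
  worst <- 0
  for (i in 1:2000) {
    worst <- max(worst, circularity(random_simple_polygon(4))$C)
  }
  expect_lte(worst, pi / 4 + 1e-9)
})

test_that("polygon ordering follows the fixed convention", {
  sq <- rbind(bigger_redder = c(1, 1), bigger_greener = c(0, 1),
              smaller_greener = c(0, 0), smaller_redder = c(1, 0))
  # shuffled rownames are restored to convention order
  p <- polygon_from(sq[c(3, 1, 4, 2), ], "goal_square")
  expect_equal(rownames(p$vertices), condition_order("goal_square"))
  expect_equal(circularity(p)$C, pi / 4, tolerance = 1e-12)

  # the crossed order (a bow-tie) collapses the shoelace area
  bow <- sq[c(1, 3, 2, 4), ]
  expect_lt(circularity(polygon_from(unname(bow), "custom"))$area, 1e-12)

  hex <- polygon_from(
    rbind(s1_c1 = c(-1, -1), s2_c1 = c(0, -1), s3_c1 = c(1, -1),
          s3_c3 = c(1, 1), s2_c3 = c(0, 1), s1_c3 = c(-1, 1)),
    "stimulus_hex")
  expect_equal(nrow(hex$vertices), 6L)
  o <- shoelace_oracle(hex$vertices)
  expect_equal(as.numeric(o$area), 4)  # convex perimeter walk of the 3 x 2 grid
  expect_error(polygon_from(sq, "weird"), class = "configuration_error")
})

test_that("subspace fit recovers a planted 2D plane", {
  set.seed(41)
  # balanced embedding: equiangular unit rows keep standardization uniform
  k <- 12
  phi <- runif(1) + pi * (0:(k - 1)) / k
  A <- sqrt(2 / k) * cbind(cos(phi), sin(phi))
  lat <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) / 2
  m <- lat %*% t(A)
  fs <- fit_subspace(m)
  expect_equal(dim(fs$components), c(2L, k))
  expect_equal(tcrossprod(fs$components), diag(2), tolerance = 1e-9)
  # projected pairwise distances proportional to the latent ones
  dl <- as.vector(dist(lat))
  dp <- as.vector(dist(fs$scores))
  expect_equal(dp / dp[1], dl / dl[1], tolerance = 1e-9)
  expect_error(fit_subspace(m[1:2, ]), class = "degenerate_input_error")
})

test_that("zero-variance channels are zeroed, not dropped", {
  set.seed(51)
  m <- matrix(rnorm(4 * 6), 4)
  m2 <- cbind(m, 7)      # constant channel
  c1 <- circularity(polygon_from(fit_subspace(m)$scores, "custom"))$C
  c2 <- circularity(polygon_from(fit_subspace(m2)$scores, "custom"))$C
  expect_equal(c2, c1, tolerance = 1e-12)
  expect_equal(fit_subspace(m2)$components[, 7], c(0, 0))

  # identical rows: all projections coincide, circularity 0
  flat <- matrix(1, 4, 6) + 0
  expect_equal(circularity(polygon_from(fit_subspace(flat)$scores, "custom"))$C, 0)
})

test_that("top-2 PCA beats random orthonormal 2-frames", {
  set.seed(61)
  m <- matrix(rnorm(5 * 20), 5)
  z <- scale(m)
  z[is.na(z)] <- 0
  fs <- fit_subspace(m)
  v_pca <- sum(fs$scores^2)
  for (i in 1:50) {
    q <- qr.Q(qr(matrix(rnorm(20 * 2), 20)))
    expect_lte(sum((z %*% q)^2), v_pca + 1e-9)
  }
})

test_that("projection uses the fitting standardization", {
  set.seed(71)
  m <- matrix(rnorm(4 * 8), 4, dimnames = list(NULL, paste0("ch", 1:8)))
  fs <- fit_subspace(m)
  expect_equal(project_conditions(fs, m), fs$scores, tolerance = 1e-12)
  expect_error(project_conditions(fs, m[, 1:5]),
               class = "incompatible_space_error")
  m2 <- m
  colnames(m2) <- paste0("other", 1:8)
  expect_error(project_conditions(fs, m2), class = "incompatible_space_error")
})

test_that("condition averaging matches a brute-force loop", {
  set.seed(81)
  # constant per condition: mean is that constant
  lab <- factor(rep(c("a", "b", "c", "d"), each = 2))
  x <- matrix(rep(1:8, each = 3), 8, 3, byrow = FALSE)
  x[] <- as.numeric(rep(as.integer(lab), 3))
  expect_equal(unname(condition_average(x, lab)),
               matrix(1:4, 4, 3) + 0)

  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 3)
  ep <- generate_epochs(tt, list(goal = goal_square_geometry(n_channels = 6, seed = 4)),
                        n_channels = 6, noise_sd = 1, seed = 4)
  cm <- condition_average(ep, goal_labels(tt), window = c(400, 1700))
  # brute force: per-trial slice mean, then per-condition mean
  sel <- ep$times >= 400 & ep$times < 1700
  lab <- goal_labels(tt)
  for (g in levels(lab)) {
    ii <- which(lab == g)
    man <- colMeans(do.call(rbind, lapply(ii, function(i)
      rowMeans(ep$data[i, , sel]))))
    expect_equal(unname(cm[g, ]), unname(man), tolerance = 1e-12)
  }
  expect_error(condition_average(ep, lab, window = c(9000, 9500)),
               class = "invalid_parameter_error")
  expect_error(condition_average(x[1:6, ], factor(lab[1:6], levels = letters[1:5])),
               class = "missing_condition_error")
})

test_that("compiled condition-matrix circularity agrees with the R path", {
  set.seed(91)
  for (i in 1:20) {
    m <- matrix(rnorm(4 * 10), 4)
    viaR <- circularity(polygon_from(fit_subspace(m)$scores, "custom"))$C
    expect_equal(geomstate:::cpp_condmat_circularity(m), viaR,
                 tolerance = 1e-9)
    expect_equal(geomstate:::condmat_circularity(m), viaR, tolerance = 1e-9)
  }
})
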