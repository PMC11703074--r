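#' Spherical searchlight neighborhoods
#'
#' For each in-mask voxel, the linear indices of in-mask voxels whose
#' center-to-center distance is at most \code{radius_mm} (inclusive).
#' Spheres clipped at mask edges retain their in-mask members only.
#' With 3-mm isotropic voxels and a 9-mm radius an interior sphere holds
#' 123 voxels.
#'
#' @param mask logical 3D array of in-brain voxels.
#' @param voxel_size isotropic voxel size in mm.
#' @param radius_mm sphere radius in mm (default 9; must be >= voxel size).
#' @return named list: per in-mask voxel (name = its linear index) an
#'   integer vector of member linear indices.
#' @export
sphere_neighborhoods <- function(mask, voxel_size = 3, radius_mm = 9) {
  if (!any(mask))
    abort_geomstate("the mask is empty", "invalid_mask_error")
  if (radius_mm < voxel_size)
    abort_geomstate("radius must be at least one voxel", "invalid_parameter_error")
  dims <- dim(mask)
  r_vox <- floor(radius_mm / voxel_size)
  off <- expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox)
  off <- off[sqrt(rowSums(off^2)) * voxel_size <= radius_mm, , drop = FALSE]
  centers <- which(mask, arr.ind = TRUE)
  center_lin <- which(mask)
  n_off <- nrow(off)
  # centers x offsets matrix of member linear indices (NA out of bounds)
  memb <- matrix(NA_integer_, nrow(centers), n_off)
  for (k in seq_len(n_off)) {
    x <- centers[, 1] + off$dx[k]
    y <- centers[, 2] + off$dy[k]
    z <- centers[, 3] + off$dz[k]
    ok <- x >= 1 & x <= dims[1] & y >= 1 & y <= dims[2] & z >= 1 & z <= dims[3]
    lin <- ifelse(ok, x + (y - 1L) * dims[1] + (z - 1L) * dims[1] * dims[2],
                  NA_integer_)
    valid <- which(!is.na(lin))
    lin[valid[!mask[lin[valid]]]] <- NA_integer_
    memb[, k] <- lin
  }
  out <- lapply(seq_len(nrow(memb)), function(i) {
    v <- memb[i, ]
    as.integer(v[!is.na(v)])
  })
  names(out) <- as.character(center_lin)
  out
}

#' Searchlight circularity map
#'
#' Runs the condition-geometry pipeline (condition means, channel-wise
#' standardization, PCA, projection, fixed-order polygon, circularity)
#' inside every searchlight sphere, with voxels playing the role of
#' channels.
#'
#' @param betas a \code{beta_volume} (see [generate_beta_volumes()]).
#' @param labels per-trial condition factor (levels in polygon order);
#'   defaults to the goal labels stored in the volume.
#' @param spheres neighborhoods from [sphere_neighborhoods()]; computed
#'   from the volume's mask when NULL.
#' @param order_label polygon order convention.
#' @param radius_mm sphere radius when spheres are computed here.
#' @return object of class \code{searchlight_map}: 3D array of
#'   circularity values (NA outside the mask; spheres with fewer than 3
#'   voxels are set NA), plus \code{radius_mm}, \code{voxel_size}.
#' @export
searchlight_circularity <- function(betas, labels = NULL, spheres = NULL,
                                    order_label = "goal_square",
                                    radius_mm = 9) {
  if (is.null(labels)) labels <- betas$labels
  labels <- factor(labels, levels = condition_order(order_label))
  if (anyNA(labels))
    abort_geomstate("labels contain conditions outside the polygon order",
                    "missing_condition_error")
  if (is.null(spheres))
    spheres <- sphere_neighborhoods(betas$mask, betas$voxel_size, radius_mm)
  dims <- dim(betas$mask)
  n_trials <- dim(betas$data)[4]
  flat <- matrix(betas$data, prod(dims), n_trials)   # voxels x trials
  counts <- table(labels)
  if (any(counts == 0))
    abort_geomstate("every condition must be present", "missing_condition_error")
  cm <- rowsum(t(flat), labels) / as.vector(counts)  # conditions x voxels
  vals <- array(NA_real_, dims)
  cv <- cpp_sphere_circularity(cm, unname(spheres))
  vals[as.integer(names(spheres))] <- cv
  small <- sum(lengths(spheres) < 3L)
  if (small > 0L)
    message(sprintf("searchlight: %d sphere(s) smaller than 3 voxels set to NA", small))
  structure(list(values = vals, radius_mm = radius_mm,
                 voxel_size = betas$voxel_size),
            class = "searchlight_map")
}

# connected components under face (6-)adjacency in a logical 3D array
#' @keywords internal
label_components_3d <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  shift <- c(-1L, 1L, -dims[1], dims[1], -dims[1] * dims[2], dims[1] * dims[2])
  nvox <- prod(dims)
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      i <- (v - 1L) %% dims[1] + 1L
      j <- ((v - 1L) %/% dims[1]) %% dims[2] + 1L
      for (s in seq_along(shift)) {
        w <- v + shift[s]
        if (w < 1L || w > nvox) next
        # reject wrap-around across x and y faces
        if (s <= 2L && ((s == 1L && i == 1L) || (s == 2L && i == dims[1]))) next
        if (s %in% 3:4 && ((s == 3L && j == 1L) || (s == 4L && j == dims[2]))) next
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

#' Group-level cluster correction for searchlight maps
#'
#' The group null is built by bootstrapping subject label-shuffled maps:
#' each draw picks one random permuted map per subject and averages them.
#' Voxelwise p-values of the true group mean against the null give
#' supra-threshold voxels at \code{voxel_alpha}; those are clustered by
#' face adjacency, and the cluster-size threshold is the (1 - alpha)
#' quantile of the maximal cluster size over the null draws (thresholded
#' the same way).
#'
#' @param true_maps list of per-subject \code{searchlight_map}s (or 3D
#'   arrays).
#' @param perm_maps list (subjects) of lists of permuted maps, e.g. from
#'   [searchlight_permuted_maps()].
#' @param n_bootstrap bootstrap draws (default 10000; scaled-down preset
#'   500).
#' @param voxel_alpha voxelwise alpha (default 0.01).
#' @param alpha cluster-level alpha (default 0.05).
#' @param seed integer seed.
#' @return object of class \code{group_clusters}: \code{group_map},
#'   \code{p_map}, \code{supra} (logical array), \code{clusters}
#'   (data.frame size, p, center of mass), \code{cluster_threshold},
#'   \code{label_map}.
#' @export
group_cluster_correction <- function(true_maps, perm_maps,
                                     n_bootstrap = 10000L, voxel_alpha = 0.01,
                                     alpha = 0.05, seed = 1L) {
  getv <- function(m) if (inherits(m, "searchlight_map")) m$values else m
  tmaps <- lapply(true_maps, getv)
  pmaps <- lapply(perm_maps, function(s) lapply(s, getv))
  n_s <- length(tmaps)
  if (length(pmaps) != n_s)
    abort_geomstate("permuted maps must be supplied for every subject",
                    "invalid_parameter_error")
  dims <- dim(tmaps[[1]])
  inmask <- which(!is.na(tmaps[[1]]))
  tv <- vapply(tmaps, function(m) m[inmask], numeric(length(inmask)))
  group_true <- rowMeans(tv)
  pv <- lapply(pmaps, function(s)
    vapply(s, function(m) m[inmask], numeric(length(inmask))))
  n_perm_each <- vapply(pv, ncol, 0L)
  null_mat <- with_seed(split_seed(seed, 211L), {
    out <- matrix(NA_real_, length(inmask), n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      acc <- numeric(length(inmask))
      for (s in seq_len(n_s))
        acc <- acc + pv[[s]][, sample.int(n_perm_each[s], 1L)]
      out[, b] <- acc / n_s
    }
    out
  })
  # voxelwise p and threshold from the null draws
  p_vox <- (rowSums(null_mat >= group_true) + 1) / (n_bootstrap + 1)
  vthr <- apply(null_mat, 1, stats::quantile, probs = 1 - voxel_alpha,
                names = FALSE)
  supra_vec <- group_true > vthr
  max_size <- function(vec) {
    m <- array(FALSE, dims); m[inmask] <- vec
    lab <- label_components_3d(m)
    if (!any(lab > 0)) 0L else max(tabulate(lab[lab > 0]))
  }
  null_max <- vapply(seq_len(n_bootstrap), function(b)
    max_size(null_mat[, b] > vthr), 0L)
  cthr <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  supra <- array(FALSE, dims); supra[inmask] <- supra_vec
  lab <- label_components_3d(supra)
  cl <- data.frame()
  if (any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > cthr)
    if (length(keep)) {
      cl <- do.call(rbind, lapply(keep, function(k) {
        vox <- which(lab == k, arr.ind = TRUE)
        data.frame(cluster = k, size = sizes[k],
                   p = mean(null_max >= sizes[k]),
                   cx = mean(vox[, 1]), cy = mean(vox[, 2]), cz = mean(vox[, 3]))
      }))
    }
    lab[!(lab %in% keep)] <- 0L
  }
  gm <- array(NA_real_, dims); gm[inmask] <- group_true
  pm <- array(NA_real_, dims); pm[inmask] <- p_vox
  structure(list(group_map = gm, p_map = pm, supra = supra, clusters = cl,
                 cluster_threshold = cthr, label_map = lab,
                 voxel_alpha = voxel_alpha, alpha = alpha),
            class = "group_clusters")
}

#' Label-shuffled searchlight maps for one subject
#'
#' @param betas a \code{beta_volume}.
#' @param labels per-trial condition factor.
#' @param spheres precomputed neighborhoods (shared across shuffles).
#' @param n_shuffles number of label shuffles (default 100; scaled-down
#'   preset 20).
#' @param order_label polygon order convention.
#' @param seed integer seed.
#' @return list of \code{searchlight_map}s.
#' @export
searchlight_permuted_maps <- function(betas, labels = NULL, spheres = NULL,
                                      n_shuffles = 100L,
                                      order_label = "goal_square", seed = 1L) {
  if (is.null(labels)) labels <- betas$labels
  if (is.null(spheres))
    spheres <- sphere_neighborhoods(betas$mask, betas$voxel_size)
  with_seed(split_seed(seed, 231L), {
    lapply(seq_len(n_shuffles), function(i) {
      searchlight_circularity(betas, sample(labels), spheres,
                              order_label = order_label)
    })
  })
}

#' ROI circularity robustness by trial bootstrap
#'
#' Circularity of an ROI (all its voxels as channels) averaged over
#' \code{n_boot} stratified trial-bootstrap replicates, with a p-value
#' against a label-shuffled null built the same way.
#'
#' @param betas a \code{beta_volume}.
#' @param roi integer vector of voxel linear indices (>= 3 voxels).
#' @param labels per-trial condition factor.
#' @param n_boot bootstrap replicates per estimate (default 20).
#' @param n_null label shuffles for the null (default 100).
#' @param order_label polygon order convention.
#' @param seed integer seed.
#' @return list with \code{circularity} (bootstrap mean), \code{p},
#'   \code{null} (the null estimates).
#' @export
roi_robustness <- function(betas, roi, labels = NULL, n_boot = 20L,
                           n_null = 100L, order_label = "goal_square",
                           seed = 1L) {
  if (length(roi) < 3)
    abort_geomstate("ROI must contain at least 3 voxels", "invalid_roi_error")
  if (is.null(labels)) labels <- betas$labels
  labels <- factor(labels, levels = condition_order(order_label))
  dims <- dim(betas$mask)
  flat <- matrix(betas$data, prod(dims), dim(betas$data)[4])
  x <- t(flat[roi, , drop = FALSE])                 # trials x voxels
  est_fun <- function(lab) {
    by_cond <- split(seq_len(nrow(x)), lab)
    mean(vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(by_cond, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      glab <- rep(seq_along(by_cond), lengths(by_cond))
      cmz <- rowsum(x[idx, , drop = FALSE], glab) / lengths(by_cond)
      condmat_circularity(cmz)
    }, 0))
  }
  with_seed(split_seed(seed, 251L), {
    est <- est_fun(labels)
    null <- vapply(seq_len(n_null), function(i) est_fun(sample(labels)), 0)
    list(circularity = est, p = (sum(null >= est) + 1) / (n_null + 1),
         null = null)
  })
}

#' Beta-series functional connectivity between ROIs
#'
#' Trial-wise mean beta per ROI, then the Pearson correlation across
#' trials for every ROI pair (diagonal 1). Constant ROI series yield NA
#' entries with a warning.
#'
#' @param betas a \code{beta_volume}.
#' @param rois named list of voxel linear-index vectors.
#' @return symmetric ROI x ROI correlation matrix.
#' @export
beta_series_fc <- function(betas, rois) {
  if (length(rois) < 2)
    abort_geomstate("need at least 2 ROIs", "invalid_parameter_error")
  if (dim(betas$data)[4] < 3)
    abort_geomstate("need at least 3 trials", "invalid_parameter_error")
  dims <- dim(betas$mask)
  flat <- matrix(betas$data, prod(dims), dim(betas$data)[4])
  series <- vapply(rois, function(vx) colMeans(flat[vx, , drop = FALSE]),
                   numeric(dim(betas$data)[4]))
  if (any(apply(series, 2, stats::sd) == 0))
    warning("constant ROI series: correlations undefined (NA)")
  r <- suppressWarnings(stats::cor(series))
  diag(r) <- 1
  r
}

#' Brain-behavior tests on functional connections
#'
#' For each connection in the declared family, Spearman correlation
#' across subjects between the connection strength and a behavioral or
#' geometry score, BH-adjusted within the family, optionally with a JZS
#' correlation Bayes factor (BF10) by numerical integration.
#'
#' @param fc_list list of per-subject FC matrices from [beta_series_fc()].
#' @param score per-subject numeric vector (circularity or error).
#' @param family data.frame with columns roi1, roi2 naming the
#'   connections tested together.
#' @param bayes also report BF10 (default TRUE).
#' @return data.frame with columns roi1, roi2, rho, p, p_adj (and bf10).
#' @export
fc_brain_behavior <- function(fc_list, score, family, bayes = TRUE) {
  n <- length(fc_list)
  if (n < 5 || length(score) != n)
    abort_geomstate("need paired per-subject values for >= 5 subjects",
                    "insufficient_subjects_error")
  if (!all(c("roi1", "roi2") %in% names(family)))
    abort_geomstate("family must declare roi1/roi2 columns",
                    "configuration_error")
  res <- lapply(seq_len(nrow(family)), function(i) {
    v <- vapply(fc_list, function(m) m[family$roi1[i], family$roi2[i]], 0)
    ct <- suppressWarnings(stats::cor.test(v, score, method = "spearman",
                                           exact = FALSE))
    data.frame(roi1 = family$roi1[i], roi2 = family$roi2[i],
               rho = unname(ct$estimate), p = ct$p.value,
               bf10 = if (bayes) jzs_correlation_bf(stats::cor(v, score), n)
                      else NA_real_)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' JZS correlation Bayes factor
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor for a Pearson
#' correlation, computed by numerical integration over the scale
#' hyperparameter g.
#'
#' @param r observed Pearson correlation.
#' @param n sample size (>= 4).
#' @return BF10 (evidence for a nonzero correlation over the null).
#' @export
jzs_correlation_bf <- function(r, n) {
  if (n < 4) abort_geomstate("n must be >= 4", "invalid_parameter_error")
  integrand <- function(g)
    (1 + g)^((n - 2) / 2) * (1 + (1 - r^2) * g)^(-(n - 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
}
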