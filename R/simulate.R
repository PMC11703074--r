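#' Task epoch boundaries
#'
#' The trial timeline relative to goal-cue onset: Goal cue 0-400 ms,
#' Delay 1 400-1700 ms, Sample 1700-2300 ms, Delay 2 2300-3800 ms,
#' Response 3800-4300 ms.
#'
#' @return data.frame with columns epoch, start, end (ms).
#' @export
task_epochs <- function() {
  data.frame(epoch = c("goal_cue", "delay1", "sample", "delay2", "response"),
             start = c(0, 400, 1700, 2300, 3800),
             end = c(400, 1700, 2300, 3800, 4300),
             stringsAsFactors = FALSE)
}

#' Piecewise-constant activation profile over task epochs
#'
#' Returns a function of time (ms) giving the planted geometry's gain in
#' [0, 1]: \code{gain} inside the listed task epochs, 0 elsewhere.
#'
#' @param epochs character vector of [task_epochs()] names.
#' @param gain gain inside the active epochs (default 1).
#' @return function mapping a numeric ms vector to gains.
#' @export
activation_profile <- function(epochs = "delay1", gain = 1) {
  te <- task_epochs()
  bad <- setdiff(epochs, te$epoch)
  if (length(bad))
    abort_geomstate(sprintf("unknown task epochs: %s", paste(bad, collapse = ", ")),
                    "configuration_error")
  sel <- te[te$epoch %in% epochs, , drop = FALSE]
  function(t) {
    g <- numeric(length(t))
    for (i in seq_len(nrow(sel))) g[t >= sel$start[i] & t < sel$end[i]] <- gain
    g
  }
}

#' Default synthetic channel groups
#'
#' Three groups mirroring a frontal/central/posterior montage split of
#' 16/26/17 channels. Returned as a factor over channel indices.
#'
#' @param n_channels total channel count (default 59; other counts are
#'   split proportionally).
#' @return factor of length \code{n_channels} with levels
#'   frontal/central/posterior.
#' @export
default_channel_groups <- function(n_channels = 59L) {
  if (n_channels == 59L) {
    sizes <- c(frontal = 16L, central = 26L, posterior = 17L)
  } else {
    sizes <- round(n_channels * c(frontal = 16, central = 26, posterior = 17) / 59)
    sizes[3] <- n_channels - sum(sizes[1:2])
  }
  factor(rep(names(sizes), sizes), levels = c("frontal", "central", "posterior"))
}

# Balanced random loading matrix restricted to a channel subset: rows are
# equiangular unit-direction pairs (cos, sin) of equally spaced angles with
# a random offset, randomly assigned to channels and scaled so the two
# columns are exactly orthonormal. Equal row norms make the per-channel
# standardization of the geometry pipeline a uniform scaling, so planted
# shapes with isotropic latent covariance (the goal square, the stimulus
# grid) are recovered undistorted at zero noise.
#' @keywords internal
random_mixing <- function(n_channels, support = seq_len(n_channels)) {
  mx <- matrix(0, n_channels, 2)
  k <- length(support)
  if (k < 2)
    abort_geomstate("geometry needs at least 2 carrying channels",
                    "configuration_error")
  phi <- stats::runif(1, 0, pi) + pi * (seq_len(k) - 1) / k
  rows <- sqrt(2 / k) * cbind(cos(phi), sin(phi))
  rows <- rows[sample.int(k), , drop = FALSE]
  mx[support, ] <- rows
  mx
}

#' Planted latent geometries
#'
#' A planted geometry places each condition at a known 2D latent
#' coordinate, mixes the two latent axes linearly into channels (unit-norm
#' loading columns, optionally restricted to a channel group), and gates
#' the signal in time with an activation profile. \code{goal_square_geometry}
#' plants the 2 x 2 goal square; \code{stimulus_grid_geometry} the 3 x 3
#' stimulus grid (with hexagon coordinates available after dropping the
#' middle color bin).
#'
#' @param side side length of the goal square (latent units), default 1.
#' @param n_channels number of channels the mixing matrix spans.
#' @param support integer indices of channels carrying the geometry
#'   (default all).
#' @param activation function of time in ms giving gain in [0, 1]; see
#'   [activation_profile()].
#' @param snr ratio of per-channel geometry signal variance (across
#'   conditions, within the active window, averaged over carrying
#'   channels) to noise variance; \code{NULL} leaves coordinates unscaled.
#' @param seed integer seed for the random mixing matrix.
#' @return object of class \code{planted_geometry} with fields
#'   \code{coords} (condition x 2, rownames = condition ids in polygon
#'   order), \code{mixing} (channels x 2), \code{activation}, \code{snr}.
#' @export
goal_square_geometry <- function(side = 1, n_channels = 59L,
                                 support = seq_len(n_channels),
                                 activation = activation_profile(c("goal_cue", "delay1")),
                                 snr = 1, seed = 1L) {
  if (side <= 0) abort_geomstate("square side must be positive", "invalid_spec_error")
  h <- side / 2
  coords <- rbind(c(h, h), c(-h, h), c(-h, -h), c(h, -h))
  rownames(coords) <- condition_order("goal_square")
  planted_geometry(coords, n_channels, support, activation, snr, seed)
}

#' @rdname goal_square_geometry
#' @param spacing grid spacing of the stimulus lattice (latent units).
#' @export
stimulus_grid_geometry <- function(spacing = 1, n_channels = 59L,
                                   support = seq_len(n_channels),
                                   activation = activation_profile(c("sample", "delay2")),
                                   snr = 1, seed = 2L) {
  g <- expand.grid(s = 1:3, c = 1:3)
  coords <- cbind((g$s - 2) * spacing, (g$c - 2) * spacing)
  rownames(coords) <- paste0("s", g$s, "_c", g$c)
  planted_geometry(coords, n_channels, support, activation, snr, seed)
}

#' @rdname goal_square_geometry
#' @param coords explicit condition x 2 latent coordinates with condition
#'   ids as rownames.
#' @export
planted_geometry <- function(coords, n_channels = 59L,
                             support = seq_len(n_channels),
                             activation = activation_profile("delay1"),
                             snr = 1, seed = 1L) {
  coords <- as.matrix(coords)
  mixing <- with_seed(split_seed(seed, 23L), random_mixing(n_channels, support))
  structure(list(coords = coords, mixing = mixing, activation = activation,
                 snr = snr, support = support),
            class = "planted_geometry")
}

# scale factor such that the mean per-channel across-condition signal
# variance on carrying channels equals snr * noise_sd^2
#' @keywords internal
geometry_gain <- function(geom, noise_sd) {
  if (is.null(geom$snr)) return(1)
  b <- geom$mixing %*% t(geom$coords)          # channels x conditions
  v <- apply(b[geom$support, , drop = FALSE], 1, stats::var)
  vbar <- mean(v)
  if (vbar <= 0) return(1)
  sqrt(geom$snr * noise_sd^2 / vbar)
}

#' Generate synthetic multichannel epochs with planted geometry
#'
#' Each trial's signal is \code{gain_trial * activation(t) * (mixing \%*\%
#' coord(condition))} summed over the supplied geometries, plus i.i.d.
#' Gaussian noise. Geometries are scaled so their across-condition signal
#' variance on carrying channels is \code{snr * noise_sd^2}. An optional
#' theta coupling adds a seed-channel oscillation re-emitted phase-lagged
#' in the posterior group.
#'
#' @param trials a [generate_design()] trial table.
#' @param geometries named list of \code{planted_geometry} objects, keyed
#'   by the label column driving them: \code{goal} uses goal labels,
#'   \code{stimulus} uses the 3 x 3 stimulus grid labels.
#' @param n_channels channel count (default 59).
#' @param sfreq sampling frequency in Hz (default 250).
#' @param t_start,t_end epoch bounds in ms relative to goal-cue onset
#'   (defaults -500 and 4300).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param trial_gain optional per-trial signal gain (default 1); used to
#'   couple geometry strength to behavior.
#' @param theta_coupling optional list \code{(freq, lag, strength, window)}
#'   planting a seed (first frontal channel) oscillation with a
#'   phase-lagged copy in every posterior channel inside \code{window} ms.
#' @param channel_groups factor as from [default_channel_groups()].
#' @param seed integer seed.
#' @return object of class \code{epoch_array}: list with \code{data}
#'   (trials x channels x samples), \code{times} (ms), \code{sfreq},
#'   \code{channel_names}, \code{channel_groups}.
#' @export
generate_epochs <- function(trials, geometries = list(goal = goal_square_geometry()),
                            n_channels = 59L, sfreq = 250, t_start = -500,
                            t_end = 4300, noise_sd = 1, trial_gain = NULL,
                            theta_coupling = NULL,
                            channel_groups = default_channel_groups(n_channels),
                            seed = 1L) {
  if (t_end <= t_start) abort_geomstate("t_start must precede t_end",
                                        "invalid_parameter_error")
  if (sfreq <= 0) abort_geomstate("sfreq must be positive", "invalid_parameter_error")
  if (noise_sd < 0) abort_geomstate("noise_sd must be non-negative",
                                    "invalid_parameter_error")
  n_samples <- floor((t_end - t_start) * sfreq / 1000)
  times <- t_start + (seq_len(n_samples) - 1L) * 1000 / sfreq
  n_trials <- nrow(trials)
  if (is.null(trial_gain)) trial_gain <- rep(1, n_trials)

  lab_for <- function(key) {
    switch(key,
      goal = as.character(goal_labels(trials)),
      stimulus = paste0("s", trials$size_bin, "_c", trials$color_bin),
      abort_geomstate(sprintf("no label rule for geometry '%s'", key),
                      "configuration_error"))
  }

  data <- with_seed(split_seed(seed, 37L), {
    arr <- array(stats::rnorm(n_trials * n_channels * n_samples, 0, noise_sd),
                 dim = c(n_trials, n_channels, n_samples))
    for (key in names(geometries)) {
      geom <- geometries[[key]]
      if (nrow(geom$mixing) != n_channels)
        abort_geomstate("geometry mixing rows must equal n_channels",
                        "configuration_error")
      lab <- lab_for(key)
      missing <- setdiff(unique(lab), rownames(geom$coords))
      if (length(missing))
        abort_geomstate(sprintf("conditions absent from geometry coords: %s",
                                paste(missing, collapse = ", ")),
                        "missing_condition_error")
      gain <- geometry_gain(geom, noise_sd)
      act <- geom$activation(times)                     # samples
      chan_sig <- gain * geom$mixing %*% t(geom$coords) # channels x conditions
      sig_tc <- lapply(rownames(geom$coords), function(cond)
        outer(chan_sig[, cond], act))                   # channels x samples
      names(sig_tc) <- rownames(geom$coords)
      for (i in seq_len(n_trials))
        arr[i, , ] <- arr[i, , ] + trial_gain[i] * sig_tc[[lab[i]]]
    }
    if (!is.null(theta_coupling)) {
      tc <- theta_coupling
      seed_ch <- which(channel_groups == "frontal")[1]
      post_ch <- which(channel_groups == "posterior")
      win <- tc$window %||% c(1700, 3800)
      taper <- as.numeric(times >= win[1] & times < win[2])
      strength <- tc$strength %||% 1
      lag <- tc$lag %||% (pi / 4)
      for (i in seq_len(n_trials)) {
        ph <- stats::runif(1, 0, 2 * pi)
        osc <- cos(2 * pi * tc$freq * times / 1000 + ph) * taper
        osc_lag <- cos(2 * pi * tc$freq * times / 1000 + ph - lag) * taper
        arr[i, seed_ch, ] <- arr[i, seed_ch, ] + strength * osc
        arr[i, post_ch, ] <- arr[i, post_ch, ] +
          rep(strength * osc_lag, each = length(post_ch))
      }
    }
    arr
  })
  structure(list(data = data, times = times, sfreq = sfreq,
                 channel_names = sprintf("ch%02d", seq_len(n_channels)),
                 channel_groups = channel_groups),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("epoch_array: %d trials x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Subset an epoch array by channel group or index
#'
#' @param epochs an \code{epoch_array}.
#' @param channels a group name ("frontal", "central", "posterior"), or
#'   integer/character channel selection.
#' @return a new \code{epoch_array} with the selected channels.
#' @export
select_channels <- function(epochs, channels) {
  idx <- if (is.character(channels) && all(channels %in% levels(epochs$channel_groups)))
    which(epochs$channel_groups %in% channels)
  else if (is.character(channels)) match(channels, epochs$channel_names)
  else channels
  structure(list(data = epochs$data[, idx, , drop = FALSE],
                 times = epochs$times, sfreq = epochs$sfreq,
                 channel_names = epochs$channel_names[idx],
                 channel_groups = droplevels(epochs$channel_groups[idx])),
            class = "epoch_array")
}

#' Generate behavioral errors coupled to geometry strength
#'
#' Error magnitudes shrink with planted per-trial geometry strength:
#' the magnitude of each error is its baseline (mean absolute size error
#' 0.133 of starting size; mean absolute color error 10.1 steps) scaled
#' by \code{1 - coupling * strength_z} plus Gaussian noise, floored at
#' zero, with a random sign. With \code{coupling = 0} errors are
#' independent of strength; with strong coupling and little noise the
#' bottom-error quartile holds the high-strength trials.
#'
#' @param trials a trial table.
#' @param strength per-trial geometry strength (length = trial count).
#' @param coupling coupling magnitude in [0, 1); 0 = no coupling.
#' @param noise_sd error noise, as a fraction of the baseline magnitude.
#' @param strength_center,strength_scale centering/scaling used to
#'   standardize \code{strength} before coupling (defaults: its own mean
#'   and sd). Supply cohort-level values when subjects differ only in
#'   their constant per-subject strength.
#' @param seed integer seed.
#' @return the trial table with size_error, color_error, response columns
#'   and response bins filled in.
#' @export
generate_behavior <- function(trials, strength = rep(1, nrow(trials)),
                              coupling = 0, noise_sd = 0.3,
                              strength_center = NULL, strength_scale = NULL,
                              seed = 1L) {
  if (noise_sd < 0)
    abort_geomstate("noise_sd must be non-negative", "invalid_parameter_error")
  if (length(strength) != nrow(trials))
    abort_geomstate("strength must have one value per trial",
                    "invalid_parameter_error")
  n <- nrow(trials)
  ctr <- strength_center %||% mean(strength)
  scl <- strength_scale %||% stats::sd(strength)
  if (!is.finite(scl) || scl <= 0) scl <- 1
  sz <- (strength - ctr) / scl
  base_size <- 0.133; base_color <- 10.1
  trials2 <- with_seed(split_seed(seed, 53L), {
    msize <- pmax(0, base_size * (1 - coupling * sz) +
                    stats::rnorm(n, 0, noise_sd * base_size))
    mcolor <- pmax(0, base_color * (1 - coupling * sz) +
                     stats::rnorm(n, 0, noise_sd * base_color))
    ssign <- sample(c(-1, 1), n, replace = TRUE)
    csign <- sample(c(-1, 1), n, replace = TRUE)
    trials$size_error <- ssign * msize        # signed fraction of starting size
    trials$color_error <- csign * mcolor      # signed color steps
    trials$response_size <- trials$size_target + trials$size_error * trials$size_start
    trials$response_color <- trials$color_target + trials$color_error
    trials$response_size_bin <- as.integer(cut(trials$response_size,
      stats::quantile(trials$response_size, c(0, 1/3, 2/3, 1)),
      include.lowest = TRUE))
    trials$response_color_bin <- as.integer(cut(trials$response_color,
      stats::quantile(trials$response_color, c(0, 1/3, 2/3, 1)),
      include.lowest = TRUE))
    trials
  })
  trials2
}

#' Generate trial-wise beta volumes with a planted spherical ROI
#'
#' Voxels inside the planted sphere carry \code{mixing \%*\% coord(condition)}
#' plus noise; all other in-mask voxels carry pure noise. The geometry's
#' mixing matrix is drawn over the ROI voxels and scaled to the requested
#' SNR as in [generate_epochs()].
#'
#' @param trials trial table supplying goal labels.
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param voxel_size isotropic voxel size in mm.
#' @param roi_center,roi_radius planted sphere center (voxel indices,
#'   1-based) and radius in mm.
#' @param coords condition x 2 latent coordinates (default: unit goal
#'   square).
#' @param snr signal-to-noise variance ratio inside the ROI.
#' @param noise_sd noise standard deviation.
#' @param mask optional logical 3D mask (default: all voxels in-brain).
#' @param seed integer seed.
#' @return object of class \code{beta_volume}: list with \code{data}
#'   (x,y,z,trial array), \code{mask}, \code{voxel_size}, \code{labels}.
#' @export
generate_beta_volumes <- function(trials, grid_shape = c(20L, 20L, 20L),
                                  voxel_size = 3, roi_center = NULL,
                                  roi_radius = 9,
                                  coords = NULL, snr = 1, noise_sd = 1,
                                  mask = NULL, seed = 1L) {
  if (voxel_size <= 0)
    abort_geomstate("voxel_size must be positive", "invalid_parameter_error")
  grid_shape <- as.integer(grid_shape)
  if (is.null(roi_center)) roi_center <- ceiling(grid_shape / 2)
  r_vox <- roi_radius / voxel_size
  if (any(roi_center - r_vox < 1) || any(roi_center + r_vox > grid_shape))
    abort_geomstate("planted ROI must lie fully inside the grid",
                    "geometry_placement_error")
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  if (is.null(coords)) {
    coords <- rbind(c(0.5, 0.5), c(-0.5, 0.5), c(-0.5, -0.5), c(0.5, -0.5))
    rownames(coords) <- condition_order("goal_square")
  }
  lab <- as.character(goal_labels(trials))
  missing <- setdiff(unique(lab), rownames(coords))
  if (length(missing))
    abort_geomstate(sprintf("conditions absent from geometry coords: %s",
                            paste(missing, collapse = ", ")),
                    "missing_condition_error")
  idx <- which(mask, arr.ind = TRUE)
  dmm <- sweep(idx, 2L, roi_center, "-") * voxel_size
  inroi <- which(sqrt(rowSums(dmm^2)) <= roi_radius)
  n_vox <- prod(grid_shape); n_trials <- nrow(trials)
  roi_lin <- (idx[inroi, 1]) + (idx[inroi, 2] - 1L) * grid_shape[1] +
    (idx[inroi, 3] - 1L) * grid_shape[1] * grid_shape[2]
  data <- with_seed(split_seed(seed, 71L), {
    mx <- random_mixing(length(roi_lin), seq_along(roi_lin))
    b <- mx %*% t(coords)                       # roi voxels x conditions
    v <- mean(apply(b, 1, stats::var))
    gain <- if (!is.null(snr) && v > 0) sqrt(snr * noise_sd^2 / v) else 1
    flat <- matrix(stats::rnorm(n_vox * n_trials, 0, noise_sd), n_vox, n_trials)
    for (i in seq_len(n_trials))
      flat[roi_lin, i] <- flat[roi_lin, i] + gain * b[, lab[i]]
    array(flat, dim = c(grid_shape, n_trials))
  })
  structure(list(data = data, mask = mask, voxel_size = voxel_size,
                 roi_center = roi_center, roi_radius = roi_radius,
                 roi_voxels = roi_lin, labels = lab),
            class = "beta_volume")
}

#' Simulate a multi-subject cohort
#'
#' Builds \code{n_subjects} independent subjects under shared study
#' conditions, each with its own design permutation, mixing matrices and
#' noise. Per-subject geometry SNR can vary across subjects (to create
#' between-subject strength differences that behavioral correlations can
#' recover).
#'
#' @param n_subjects number of subjects.
#' @param snr scalar or per-subject vector of geometry SNR values.
#' @param coupling behavioral coupling passed to [generate_behavior()].
#' @param spec a [design_spec()]; the default full design can be scaled
#'   down via \code{reps_per_cell}.
#' @param n_channels,noise_sd,theta_strength forwarded to
#'   [generate_epochs()] (theta coupling planted when
#'   \code{theta_strength > 0}).
#' @param seed integer master seed.
#' @param ... further arguments to [generate_epochs()].
#' @return list of subjects, each a list(trials, epochs, snr).
#' @export
simulate_cohort <- function(n_subjects = 8L, snr = 1, coupling = 0,
                            spec = design_spec(), n_channels = 59L,
                            noise_sd = 1, theta_strength = 0, seed = 1L, ...) {
  snr <- rep_len(snr, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- split_seed(seed, 1000L + s)
    trials <- generate_design(spec, seed = sseed)
    geom <- goal_square_geometry(n_channels = n_channels, snr = snr[s],
                                 seed = sseed)
    theta <- if (theta_strength > 0)
      list(freq = 6, lag = pi / 4, strength = theta_strength) else NULL
    epochs <- generate_epochs(trials, geometries = list(goal = geom),
                              n_channels = n_channels, noise_sd = noise_sd,
                              theta_coupling = theta, seed = sseed, ...)
    trials <- generate_behavior(trials, strength = rep(snr[s], nrow(trials)),
                                coupling = coupling,
                                strength_center = mean(snr),
                                strength_scale = max(stats::sd(snr), 1e-12),
                                seed = sseed)
    list(trials = trials, epochs = epochs, snr = snr[s])
  })
}
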