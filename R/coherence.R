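#' Complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential with \code{n_cycles} cycles
#' (temporal sd = n_cycles / (2*pi*f)), L2-normalized.
#'
#' @param freq center frequency in Hz.
#' @param sfreq sampling frequency in Hz.
#' @param n_cycles number of cycles (default 5).
#' @return complex vector (odd length, centered).
#' @keywords internal
morlet_wavelet <- function(freq, sfreq, n_cycles = 5) {
  sd_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sd_t * sfreq)
  t <- (-half:half) / sfreq
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sd_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# same-length complex wavelet transform via FFT convolution
#' @keywords internal
wavelet_transform <- function(x, wav) {
  n <- length(x); m <- length(wav)
  nf <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(nf - n)))
  W <- stats::fft(c(wav, complex(real = numeric(nf - m))))
  y <- stats::fft(X * W, inverse = TRUE) / nf
  y[((m - 1L) %/% 2L) + seq_len(n)]
}

#' Per-epoch cross-spectra between a seed and target channels
#'
#' Time-frequency decomposition by complex Morlet convolution, then the
#' cross-spectrum S = W_seed * Conj(W_target) per epoch, frequency, target
#' and (decimated) time point.
#'
#' @param epochs an \code{epoch_array}.
#' @param seed_channel seed channel name or index.
#' @param targets target channel names/indices, or a group name such as
#'   \code{"posterior"}.
#' @param freqs frequencies in Hz (default 1:12); must be below Nyquist.
#' @param n_cycles wavelet cycles (default 5).
#' @param decim keep every \code{decim}-th sample (default 5).
#' @return object of class \code{cross_spectra}: complex array
#'   epochs x targets x freqs x times plus \code{freqs}, \code{times},
#'   \code{seed_channel}, \code{target_channels}.
#' @export
epoch_cross_spectra <- function(epochs, seed_channel, targets, freqs = 1:12,
                                n_cycles = 5, decim = 5L) {
  if (any(freqs >= epochs$sfreq / 2))
    abort_geomstate("frequencies must be below the Nyquist frequency",
                    "invalid_frequency_error")
  ch_idx <- function(ch) {
    if (is.character(ch) && all(ch %in% levels(epochs$channel_groups)))
      which(epochs$channel_groups %in% ch)
    else if (is.character(ch)) match(ch, epochs$channel_names)
    else as.integer(ch)
  }
  si <- ch_idx(seed_channel)[1]
  ti <- setdiff(ch_idx(targets), si)
  if (!length(ti))
    abort_geomstate("seed channel cannot be its own target",
                    "invalid_parameter_error")
  keep_t <- seq(1L, length(epochs$times), by = decim)
  wavs <- lapply(freqs, morlet_wavelet, sfreq = epochs$sfreq,
                 n_cycles = n_cycles)
  n_ep <- dim(epochs$data)[1]
  S <- array(complex(1), c(n_ep, length(ti), length(freqs), length(keep_t)))
  for (e in seq_len(n_ep)) {
    for (f in seq_along(freqs)) {
      ws <- wavelet_transform(epochs$data[e, si, ], wavs[[f]])[keep_t]
      for (j in seq_along(ti)) {
        wt <- wavelet_transform(epochs$data[e, ti[j], ], wavs[[f]])[keep_t]
        S[e, j, f, ] <- ws * Conj(wt)
      }
    }
  }
  structure(list(S = S, freqs = freqs, times = epochs$times[keep_t],
                 seed_channel = epochs$channel_names[si],
                 target_channels = epochs$channel_names[ti]),
            class = "cross_spectra")
}

#' Weighted phase-lag index map
#'
#' wPLI = |E[Im(S)]| / E[|Im(S)|] across epochs per (target, frequency,
#' time) cell, then averaged over target channels. Cells where
#' E[|Im(S)|] = 0 are set to 0. The statistic lives in [0, 1] and is
#' insensitive to zero-lag (volume-conduction-like) coupling, whose
#' cross-spectra have symmetric imaginary parts.
#'
#' @param cs a [epoch_cross_spectra()] result.
#' @return object of class \code{coherence_map}: \code{wpli} (freqs x
#'   times), \code{freqs}, \code{times}, \code{seed_channel},
#'   \code{target_channels}.
#' @export
wpli <- function(cs) {
  if (dim(cs$S)[1] < 2)
    abort_geomstate("wPLI needs at least 2 epochs", "insufficient_data_error")
  im <- Im(cs$S)
  num <- abs(apply(im, c(2, 3, 4), mean))
  den <- apply(abs(im), c(2, 3, 4), mean)
  w <- num / den
  w[den == 0] <- 0
  map <- apply(w, c(2, 3), mean)   # average over targets
  dimnames(map) <- list(paste0(cs$freqs, "Hz"), NULL)
  structure(list(wpli = map, freqs = cs$freqs, times = cs$times,
                 seed_channel = cs$seed_channel,
                 target_channels = cs$target_channels),
            class = "coherence_map")
}

#' Seed-to-target wPLI map in one call
#'
#' @inheritParams epoch_cross_spectra
#' @return a \code{coherence_map}.
#' @export
wpli_map <- function(epochs, seed_channel = "ch01", targets = "posterior",
                     freqs = 1:12, n_cycles = 5, decim = 5L) {
  wpli(epoch_cross_spectra(epochs, seed_channel, targets, freqs,
                           n_cycles, decim))
}

# subtract the per-frequency baseline mean
#' @keywords internal
baseline_correct_map <- function(map, baseline_window) {
  sel <- map$times >= baseline_window[1] & map$times < baseline_window[2]
  if (!any(sel))
    abort_geomstate("baseline window lies outside the epoch",
                    "invalid_window_error")
  map$wpli <- map$wpli - rowMeans(map$wpli[, sel, drop = FALSE])
  map
}

# connected components under 4-adjacency in a 2D logical matrix;
# returns an integer label matrix (0 = background)
#' @keywords internal
label_components_2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      r <- (v - 1L) %% nr + 1L; c <- (v - 1L) %/% nr + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > ncol(mask)) next
        w <- (nb[2] - 1L) * nr + nb[1]
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

#' Cluster permutation test on subject coherence maps
#'
#' Per-frequency baseline correction, then a one-sample one-tailed
#' cluster permutation across subjects by sign flipping: cells with
#' t > t_crit form 4-adjacent clusters in the time-frequency plane whose
#' mass (summed t) is compared with the permutation distribution of the
#' maximal cluster mass. Significant clusters are returned with their
#' theta-band (4-7 Hz) submasks.
#'
#' @param maps list of \code{coherence_map}s, one per subject (>= 5).
#' @param baseline_window \code{c(start, end)} ms (default -500..0).
#' @param alpha cluster-forming and cluster-level alpha (default 0.05).
#' @param n_perm sign-flip permutations (default 500).
#' @param theta_band frequency range for the submask (default c(4, 7)).
#' @param seed integer seed.
#' @return object of class \code{coherence_clusters}: list of clusters
#'   (mask, theta_submask, mass, p, freq_range, time_range), plus the
#'   group t map and the baseline-corrected subject array.
#' @export
coherence_cluster_test <- function(maps, baseline_window = c(-500, 0),
                                   alpha = 0.05, n_perm = 500L,
                                   theta_band = c(4, 7), seed = 1L) {
  if (length(maps) < 5)
    abort_geomstate("need at least 5 subjects", "insufficient_subjects_error")
  bc <- lapply(maps, baseline_correct_map, baseline_window = baseline_window)
  freqs <- bc[[1]]$freqs; times <- bc[[1]]$times
  arr <- simplify2array(lapply(bc, `[[`, "wpli"))   # f x t x subj
  n_s <- dim(arr)[3]
  tmap_of <- function(a) {
    mu <- apply(a, c(1, 2), mean)
    s <- apply(a, c(1, 2), stats::sd)
    tm <- mu / (s / sqrt(n_s))
    tm[!is.finite(tm)] <- 0
    tm
  }
  tcrit <- stats::qt(1 - alpha, df = n_s - 1)
  mass_of <- function(tm) {
    lab <- label_components_2d(tm > tcrit)
    if (!any(lab > 0)) return(list(lab = lab, mass = numeric(0)))
    mass <- vapply(seq_len(max(lab)), function(k) sum(tm[lab == k]), 0)
    list(lab = lab, mass = mass)
  }
  tm_true <- tmap_of(arr)
  true_cl <- mass_of(tm_true)
  null_max <- with_seed(split_seed(seed, 191L), {
    vapply(seq_len(n_perm), function(p) {
      flips <- sample(c(-1, 1), n_s, replace = TRUE)
      a <- sweep(arr, 3L, flips, "*")
      m <- mass_of(tmap_of(a))$mass
      if (length(m)) max(m) else 0
    }, 0)
  })
  clusters <- list()
  theta_rows <- which(freqs >= theta_band[1] & freqs <= theta_band[2])
  for (k in seq_along(true_cl$mass)) {
    p <- mean(null_max >= true_cl$mass[k])
    if (p > alpha) next
    mask <- true_cl$lab == k
    sub <- mask
    sub[setdiff(seq_along(freqs), theta_rows), ] <- FALSE
    ridx <- which(rowSums(mask) > 0); cidx <- which(colSums(mask) > 0)
    clusters[[length(clusters) + 1L]] <- list(
      mask = mask, theta_submask = sub, mass = true_cl$mass[k], p = p,
      freq_range = range(freqs[ridx]), time_range = range(times[cidx]))
  }
  structure(list(clusters = clusters, t_map = tm_true, freqs = freqs,
                 times = times, subject_maps = bc, alpha = alpha),
            class = "coherence_clusters")
}

#' Cluster-masked coherence strength for one subject
#'
#' Mean baseline-corrected wPLI over the (theta sub)mask cells of a
#' significant group cluster.
#'
#' @param map the subject's baseline-corrected \code{coherence_map}.
#' @param mask logical freq x time mask (use a cluster's
#'   \code{theta_submask}).
#' @return scalar strength.
#' @export
cluster_masked_strength <- function(map, mask) {
  if (!any(mask))
    abort_geomstate("the mask is empty", "empty_mask_error")
  mean(map$wpli[mask])
}

#' Correlate coherence strength with geometry across subjects
#'
#' One-tailed (positive) Spearman correlation between subjects' masked
#' coherence strengths and their circularity indices per task epoch,
#' BH-adjusted within the tested family. The same path serves the
#' delta-band control by supplying a delta submask strength.
#'
#' @param strengths numeric vector of per-subject coherence strengths.
#' @param circ matrix/data.frame subjects x epochs of circularity.
#' @return data.frame with columns epoch, rho, p, p_adj.
#' @export
coherence_geometry_correlation <- function(strengths, circ) {
  circ <- as.data.frame(circ)
  if (length(strengths) < 5)
    abort_geomstate("need at least 5 subjects", "insufficient_subjects_error")
  res <- lapply(names(circ), function(cn) {
    ct <- suppressWarnings(stats::cor.test(strengths, circ[[cn]],
                                           method = "spearman",
                                           alternative = "greater",
                                           exact = FALSE))
    data.frame(epoch = cn, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
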