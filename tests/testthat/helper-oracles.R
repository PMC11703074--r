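# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own vectorized/compiled code paths.

# plain-loop shoelace area, edge-sum perimeter, circularity
shoelace_oracle <- function(v) {
  n <- nrow(v)
  area2 <- 0
  per <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    area2 <- area2 + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
    per <- per + sqrt(sum((v[j, ] - v[i, ])^2))
  }
  area <- abs(area2) / 2
  list(area = area, perimeter = per,
       C = if (per == 0) 0 else 4 * pi * area / per^2)
}

# a random simple polygon: iid points ordered by angle around the centroid
random_simple_polygon <- function(n = 4) {
  p <- cbind(runif(n), runif(n))
  ctr <- colMeans(p)
  p[order(atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])), , drop = FALSE]
}

# tiny epoch_array built directly from a trials x channels x samples array
make_epochs <- function(data, sfreq = 250, t_start = 0,
                        groups = NULL) {
  nch <- dim(data)[2]
  if (is.null(groups))
    groups <- factor(rep("frontal", nch),
                     levels = c("frontal", "central", "posterior"))
  structure(list(
    data = data,
    times = t_start + (seq_len(dim(data)[3]) - 1) * 1000 / sfreq,
    sfreq = sfreq,
    channel_names = sprintf("ch%02d", seq_len(nch)),
    channel_groups = groups), class = "epoch_array")
}

# two-channel epochs with per-epoch signals from a generator function
# gen() -> list(a =, b =) added onto weak noise
make_pair_epochs <- function(n_ep, n_samp, sfreq, gen, noise_sd = 0.1) {
  d <- array(rnorm(n_ep * 2 * n_samp, 0, noise_sd), c(n_ep, 2, n_samp))
  for (e in seq_len(n_ep)) {
    s <- gen()
    d[e, 1, ] <- d[e, 1, ] + s$a
    d[e, 2, ] <- d[e, 2, ] + s$b
  }
  make_epochs(d, sfreq = sfreq,
              groups = factor(c("frontal", "posterior"),
                              levels = c("frontal", "central", "posterior")))
}
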