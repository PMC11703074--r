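#' Partition an epoch into non-overlapping windows
#'
#' Contiguous windows of fixed length anchored at the epoch start;
#' a trailing partial window is dropped. The default trial epoch
#' (-500 to 4300 ms, 80-ms windows) tiles into 60 windows.
#'
#' @param epoch_start,epoch_end epoch bounds in ms.
#' @param window window length in ms (default 80).
#' @return data.frame with columns start, end, center (ms).
#' @export
window_partition <- function(epoch_start = -500, epoch_end = 4300, window = 80) {
  if (window <= 0)
    abort_geomstate("window length must be positive", "invalid_parameter_error")
  if (epoch_end <= epoch_start)
    abort_geomstate("epoch_end must exceed epoch_start", "invalid_parameter_error")
  k <- floor((epoch_end - epoch_start) / window)
  start <- epoch_start + (seq_len(k) - 1) * window
  data.frame(start = start, end = start + window, center = start + window / 2)
}

# per-trial window means: trials x channels x n_windows
#' @keywords internal
window_means <- function(epochs, windows) {
  d <- epochs$data
  nw <- nrow(windows)
  out <- array(NA_real_, c(dim(d)[1], dim(d)[2], nw))
  for (w in seq_len(nw)) {
    sel <- epochs$times >= windows$start[w] & epochs$times < windows$end[w]
    out[, , w] <- rowMeans(d[, , sel, drop = FALSE], dims = 2)
  }
  out
}

# core engine: mean circularity per window over stratified bootstrap
# resamples. wm: trials x channels x windows; labels: factor whose level
# order is the polygon order. Thin wrapper over the compiled kernel.
#' @keywords internal
tc_engine <- function(wm, labels, n_resamples = 10L) {
  dm <- dim(wm)
  if (any(table(labels) == 0))
    abort_geomstate("every condition must be present", "missing_condition_error")
  m <- matrix(wm, nrow = dm[1])
  as.numeric(cpp_tc_curve(m, as.integer(labels) - 1L, nlevels(labels),
                          dm[2], as.integer(n_resamples)))
}

# plain-R reference implementation of the same engine, kept as an
# independent path for tests
#' @keywords internal
tc_engine_r <- function(wm, labels, n_resamples = 10L) {
  dm <- dim(wm)
  n_trials <- dm[1]; n_ch <- dm[2]; nw <- dm[3]
  m <- matrix(wm, nrow = n_trials)          # trials x (ch*window)
  lev <- levels(labels)
  by_cond <- split(seq_len(n_trials), labels)
  counts <- lengths(by_cond)
  if (any(counts == 0))
    abort_geomstate("every condition must be present", "missing_condition_error")
  acc <- numeric(nw)
  for (r in seq_len(n_resamples)) {
    idx <- unlist(lapply(by_cond, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]), use.names = FALSE)
    glab <- rep(seq_along(lev), counts)
    cs <- rowsum(m[idx, , drop = FALSE], glab, reorder = TRUE) / as.vector(counts)
    for (w in seq_len(nw)) {
      x <- cs[, ((w - 1L) * n_ch + 1L):(w * n_ch), drop = FALSE]
      acc[w] <- acc[w] + condmat_circularity(x)
    }
  }
  acc / n_resamples
}

#' Time-resolved circularity with stratified resampling
#'
#' For every window the trials are averaged within condition, the 2D
#' subspace fit by PCA, the conditions projected and connected in the
#' fixed order, and the circularity computed. To stabilize the estimate,
#' trials are resampled in a stratified manner (bootstrap within
#' condition, preserving per-condition counts) \code{n_resamples} times
#' and the resulting time courses averaged.
#'
#' @param epochs an \code{epoch_array}.
#' @param labels per-trial condition factor (levels in polygon order, see
#'   [condition_order()]); trials with \code{NA} labels are dropped.
#' @param order_label polygon order convention (default "goal_square").
#' @param window_ms window length in ms (default 80).
#' @param n_resamples stratified resamples (default 10).
#' @param seed integer seed for the resampling.
#' @return object of class \code{circ_timecourse}: list with
#'   \code{values}, \code{window_centers}, \code{windows},
#'   \code{window_length}, \code{n_resamples}.
#' @export
timecourse_circularity <- function(epochs, labels, order_label = "goal_square",
                                   window_ms = 80, n_resamples = 10L,
                                   seed = 1L) {
  if (n_resamples < 1)
    abort_geomstate("n_resamples must be >= 1", "invalid_parameter_error")
  labels <- factor(labels, levels = condition_order(order_label))
  keep <- !is.na(labels)
  ep <- epochs; ep$data <- ep$data[keep, , , drop = FALSE]
  labels <- droplevels(factor(labels[keep], levels = levels(labels)))
  labels <- factor(labels, levels = condition_order(order_label))
  windows <- window_partition(min(epochs$times),
                              max(epochs$times) + 1000 / epochs$sfreq, window_ms)
  wm <- window_means(ep, windows)
  vals <- with_seed(split_seed(seed, 101L), tc_engine(wm, labels, n_resamples))
  structure(list(values = vals, window_centers = windows$center,
                 windows = windows, window_length = window_ms,
                 n_resamples = n_resamples),
            class = "circ_timecourse")
}

#' Label-shuffle permutation null for the circularity time course
#'
#' Trial labels are shuffled independently within each subject and the
#' full time-course pipeline (including the stratified resampling
#' protocol) is repeated; per-iteration subject curves are averaged into
#' one null group curve. With a single subject the null is that subject's
#' own shuffled-label distribution.
#'
#' @param epochs_list one \code{epoch_array} or a list of them (subjects).
#' @param labels_list matching condition factor or list of factors.
#' @param order_label polygon order convention.
#' @param n_perm number of permutations (default 5000; the scaled-down
#'   preset uses 500). Fewer than 100 triggers a warning about unstable
#'   tail quantiles.
#' @param n_resamples stratified resamples per iteration (default 10).
#' @param window_ms window length in ms.
#' @param seed integer seed.
#' @return matrix n_perm x n_windows of null group curves.
#' @export
permutation_null <- function(epochs_list, labels_list, order_label = "goal_square",
                             n_perm = 5000L, n_resamples = 10L, window_ms = 80,
                             seed = 1L) {
  if (inherits(epochs_list, "epoch_array")) {
    epochs_list <- list(epochs_list)
    labels_list <- list(labels_list)
  }
  if (n_perm < 100)
    warning("fewer than 100 permutations: tail quantiles will be unstable")
  prep <- lapply(seq_along(epochs_list), function(s) {
    labels <- factor(labels_list[[s]], levels = condition_order(order_label))
    keep <- !is.na(labels)
    ep <- epochs_list[[s]]
    windows <- window_partition(min(ep$times), max(ep$times) + 1000 / ep$sfreq,
                                window_ms)
    ep$data <- ep$data[keep, , , drop = FALSE]
    list(wm = window_means(ep, windows),
         labels = factor(as.character(labels[keep]),
                         levels = condition_order(order_label)))
  })
  if (length(unique(vapply(prep, function(p) dim(p$wm)[3], 0L))) != 1)
    abort_geomstate("subjects disagree on window count",
                    "incompatible_timecourse_error")
  with_seed(split_seed(seed, 131L), {
    per_subj <- lapply(prep, function(p) {
      dm <- dim(p$wm)
      if (any(table(p$labels) == 0))
        abort_geomstate("every condition must be present",
                        "missing_condition_error")
      cpp_perm_null(matrix(p$wm, nrow = dm[1]), as.integer(p$labels) - 1L,
                    nlevels(p$labels), dm[2], as.integer(n_perm),
                    as.integer(n_resamples))
    })
    Reduce(`+`, per_subj) / length(per_subj)
  })
}

# maximal runs of TRUE; returns data.frame(start, end, size)
#' @keywords internal
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], size = r$lengths[keep])
}

#' Cluster-based permutation test on a time course
#'
#' Windows where the observed curve exceeds the pointwise (1 - alpha)
#' null quantile form candidate clusters (maximal supra-threshold runs);
#' the cluster statistic is the run length. The cluster-level null is the
#' per-iteration largest run length of the null curves thresholded the
#' same way; a cluster is significant when its length exceeds the
#' (1 - alpha) quantile of that null.
#'
#' @param true_tc a \code{circ_timecourse} or numeric vector.
#' @param null_tcs matrix of null curves from [permutation_null()].
#' @param alpha pointwise and cluster-level alpha (default 0.05).
#' @param pointwise \code{"per_window"} (default) thresholds each window at
#'   its own null quantile; \code{"pooled"} uses one quantile of all null
#'   values.
#' @return object of class \code{cluster_set}: data.frame \code{clusters}
#'   (start, end, size, p), \code{threshold} (pointwise, per window),
#'   \code{cluster_threshold}, \code{alpha}, \code{significant} (logical
#'   per cluster).
#' @export
cluster_test <- function(true_tc, null_tcs, alpha = 0.05,
                         pointwise = c("per_window", "pooled")) {
  pointwise <- match.arg(pointwise)
  x <- if (inherits(true_tc, "circ_timecourse")) true_tc$values else as.numeric(true_tc)
  if (ncol(null_tcs) != length(x))
    abort_geomstate("null curves and true curve disagree on window count",
                    "incompatible_timecourse_error")
  thr <- if (pointwise == "per_window")
    apply(null_tcs, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  else rep(stats::quantile(null_tcs, 1 - alpha, names = FALSE), length(x))
  cl <- runs_of(x > thr)
  exc <- sweep(null_tcs, 2L, thr, ">")
  max_null <- apply(exc, 1, function(row) {
    r <- rle(row); m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  cthr <- stats::quantile(max_null, 1 - alpha, names = FALSE)
  cl$p <- vapply(cl$size, function(s) mean(max_null >= s), 0)
  structure(list(clusters = cl, threshold = thr, cluster_threshold = cthr,
                 alpha = alpha,
                 significant = cl$size > cthr),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s), %d significant (cluster threshold %g windows)\n",
              nrow(x$clusters), sum(x$significant), x$cluster_threshold))
  if (nrow(x$clusters)) print(cbind(x$clusters, significant = x$significant))
  invisible(x)
}

#' Combined behavioral error
#'
#' Sum of the z-scored absolute color and size errors (standardized
#' within subject). If one error column has zero variance its z-score is
#' dropped with a warning and the combined error is the other component.
#'
#' @param trials a trial table with size_error and color_error.
#' @return numeric vector, one combined error per trial.
#' @export
combined_error <- function(trials) {
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(NULL)
    (v - mean(v)) / s
  }
  a <- zs(abs(trials$size_error))
  b <- zs(abs(trials$color_error))
  if (is.null(a) && is.null(b))
    abort_geomstate("both error columns are constant", "invalid_parameter_error")
  if (is.null(a) || is.null(b)) {
    warning("one error column has zero variance; using the other alone")
    return(if (is.null(a)) b else a)
  }
  a + b
}

#' Behavioral trial-split circularity difference
#'
#' Trials are split by combined behavioral error into good (small error)
#' and bad (large error) sets -- bottom/top quartiles, or a median split
#' when the quartile sets cannot cover every condition (mandatory for the
#' 6-condition stimulus geometry). Condition means of both sets are
#' projected into a subspace fit on ALL trials per window ("whole-data"
#' subspace), and the per-window difference C(good) - C(bad) is tested by
#' randomly swapping good/bad assignments and re-running, using the
#' cluster machinery.
#'
#' @param epochs an \code{epoch_array}.
#' @param labels per-trial condition factor.
#' @param error per-trial combined error, see [combined_error()].
#' @param rule \code{"quartile"} (default) or \code{"median"}.
#' @param order_label polygon order convention.
#' @param window_ms window length in ms.
#' @param n_perm swap permutations for the null (default 500).
#' @param alpha cluster alpha.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (good > bad).
#' @param seed integer seed.
#' @return object of class \code{split_result}: \code{diff_timecourse},
#'   \code{window_centers}, \code{clusters} (a \code{cluster_set} on the
#'   signed or absolute difference per \code{alternative}),
#'   \code{split_rule}, \code{good_trials}, \code{bad_trials}.
#' @export
trial_split_difference <- function(epochs, labels, error,
                                   rule = c("quartile", "median"),
                                   order_label = "goal_square", window_ms = 80,
                                   n_perm = 500L, alpha = 0.05,
                                   alternative = c("two.sided", "greater"),
                                   seed = 1L) {
  rule <- match.arg(rule)
  alternative <- match.arg(alternative)
  labels <- factor(labels, levels = condition_order(order_label))
  keep <- which(!is.na(labels))
  err <- error[keep]
  labs <- droplevels(labels[keep])
  labs <- factor(as.character(labs), levels = condition_order(order_label))
  if (rule == "quartile") {
    qs <- stats::quantile(err, c(0.25, 0.75))
    good <- keep[err <= qs[1]]
    bad <- keep[err >= qs[2]]
  } else {
    md <- stats::median(err)
    good <- keep[err <= md]
    bad <- keep[err > md]
  }
  lev <- condition_order(order_label)
  cover <- function(ii) all(lev %in% labels[ii])
  if (!cover(good) || !cover(bad))
    abort_geomstate(paste("a split leaves a condition empty;",
                          "use rule = 'median' for sparse condition sets"),
                    "split_coverage_error")
  windows <- window_partition(min(epochs$times),
                              max(epochs$times) + 1000 / epochs$sfreq, window_ms)
  wm <- window_means(epochs, windows)
  n_ch <- dim(wm)[2]; nw <- dim(wm)[3]
  m <- matrix(wm, nrow = dim(wm)[1])

  # whole-data subspace per window, fit once on all labeled trials
  all_cm <- rowsum(m[keep, , drop = FALSE], labs) /
    as.vector(table(labs))
  fits <- lapply(seq_len(nw), function(w)
    fit_subspace(all_cm[lev, ((w - 1L) * n_ch + 1L):(w * n_ch), drop = FALSE]))

  diff_for <- function(good_ii, bad_ii) {
    vapply(seq_len(nw), function(w) {
      cols <- ((w - 1L) * n_ch + 1L):(w * n_ch)
      cg <- rowsum(m[good_ii, cols, drop = FALSE], droplevels(labels[good_ii])) /
        as.vector(table(droplevels(labels[good_ii])))
      cb <- rowsum(m[bad_ii, cols, drop = FALSE], droplevels(labels[bad_ii])) /
        as.vector(table(droplevels(labels[bad_ii])))
      pg <- project_conditions(fits[[w]], cg[lev, , drop = FALSE])
      pb <- project_conditions(fits[[w]], cb[lev, , drop = FALSE])
      circ_value(pg) - circ_value(pb)
    }, 0)
  }
  true_diff <- diff_for(good, bad)
  pool <- c(good, bad); ng <- length(good)
  null_diff <- with_seed(split_seed(seed, 151L), {
    out <- matrix(NA_real_, n_perm, nw)
    for (p in seq_len(n_perm)) {
      sw <- sample(pool)
      g2 <- sw[seq_len(ng)]; b2 <- sw[(ng + 1L):length(sw)]
      if (!cover(g2) || !cover(b2)) { out[p, ] <- 0; next }
      out[p, ] <- diff_for(g2, b2)
    }
    out
  })
  if (alternative == "two.sided") {
    cl <- cluster_test(abs(true_diff), abs(null_diff), alpha = alpha)
  } else {
    cl <- cluster_test(true_diff, null_diff, alpha = alpha)
  }
  structure(list(diff_timecourse = true_diff,
                 window_centers = windows$center, clusters = cl,
                 split_rule = rule, good_trials = good, bad_trials = bad,
                 alternative = alternative),
            class = "split_result")
}

#' Correlate per-subject circularity with behavioral error
#'
#' Spearman rank correlation per (epoch, channel group) cell between
#' subjects' circularity indices and behavioral errors, with
#' Benjamini-Hochberg adjustment across the tested family. Cells with a
#' constant input vector are flagged undefined and excluded from the
#' family.
#'
#' @param circ data.frame or matrix of per-subject circularity, one
#'   column per (epoch x group) cell; or a named list of such vectors.
#' @param error numeric vector of per-subject behavioral error.
#' @param alternative correlation alternative (default "two.sided").
#' @return data.frame with columns cell, n, rho, p, p_adj, defined.
#' @export
behavior_correlation <- function(circ, error, alternative = "two.sided") {
  if (is.list(circ) && !is.data.frame(circ)) circ <- as.data.frame(circ)
  circ <- as.data.frame(circ)
  if (nrow(circ) < 5)
    abort_geomstate("need at least 5 subjects", "insufficient_subjects_error")
  cells <- names(circ)
  res <- lapply(cells, function(cn) {
    v <- circ[[cn]]
    if (stats::sd(v) == 0 || stats::sd(error) == 0)
      return(data.frame(cell = cn, n = length(v), rho = NA_real_,
                        p = NA_real_, defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(v, error, method = "spearman",
                                           alternative = alternative,
                                           exact = FALSE))
    data.frame(cell = cn, n = length(v), rho = unname(ct$estimate),
               p = ct$p.value, defined = TRUE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[out$defined] <- stats::p.adjust(out$p[out$defined], method = "BH")
  out
}

#' Relabel trials by motor adjustment direction
#'
#' The motor label is the sign pair of the response adjustments relative
#' to the response object's initial values (final minus initial). Because
#' the response object starts at random feature values, these directions
#' are decoupled from the cued goal. Trials with a zero adjustment on
#' either feature are excluded (tie-broken to "no adjustment") and listed
#' in the \code{excluded} attribute.
#'
#' @param trials trial table with size_start/color_start and
#'   response_size/response_color columns.
#' @return factor of motor labels (levels in motor_square polygon order),
#'   NA for excluded trials; attribute \code{excluded} holds their ids.
#' @export
motor_relabel <- function(trials) {
  ds <- trials$response_size - trials$size_start
  dc <- trials$response_color - trials$color_start
  zero <- ds == 0 | dc == 0
  lab <- paste(ifelse(ds > 0, "bigger", "smaller"),
               ifelse(dc > 0, "redder", "greener"), sep = "_")
  lab[zero] <- NA
  out <- factor(lab, levels = condition_order("motor_square"))
  attr(out, "excluded") <- trials$trial_id[zero]
  if (any(zero))
    message(sprintf("motor_relabel: %d trial(s) with no adjustment excluded",
                    sum(zero)))
  out
}

#' Relabel trials whose response direction contradicts the cued goal
#'
#' A trial is incorrect when the direction of the adjusted feature values
#' relative to the remembered stimulus differs from the cued goal on
#' either dimension. Those trials are returned relabeled by the actual
#' direction pair, for re-running the circularity pipeline on
#' incorrect-goal trials.
#'
#' @param trials trial table with response and stimulus value columns.
#' @return the subset of incorrect trials with a new \code{actual_label}
#'   column (levels in goal polygon order); zero rows when every response
#'   matches its cue (flagged via attribute \code{empty}).
#' @export
incorrect_goal_relabel <- function(trials) {
  actual_size <- ifelse(trials$response_size - trials$size_value > 0,
                        "bigger", "smaller")
  actual_color <- ifelse(trials$response_color - trials$color_value > 0,
                         "redder", "greener")
  mismatch <- actual_size != trials$goal_size | actual_color != trials$goal_color
  out <- trials[mismatch, , drop = FALSE]
  out$actual_label <- factor(paste(actual_size, actual_color, sep = "_")[mismatch],
                             levels = condition_order("goal_square"))
  attr(out, "empty") <- !any(mismatch)
  out
}

#' Chi-square test of independence for a contingency table
#'
#' Convenience wrapper used to check that motor directions are
#' independent of cued goals (a 4 x 4 contingency table).
#'
#' @param tab contingency table or matrix of counts.
#' @return \code{htest} from [stats::chisq.test()] without continuity
#'   correction.
#' @export
independence_test <- function(tab) {
  stats::chisq.test(as.matrix(tab), correct = FALSE)
}
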