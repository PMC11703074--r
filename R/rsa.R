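#' Representational dissimilarity matrix constructor
#'
#' @param distances symmetric matrix with zero diagonal.
#' @param labels condition ids (default from dimnames).
#' @return object of class \code{rdm}.
#' @export
rdm <- function(distances, labels = rownames(distances)) {
  d <- as.matrix(distances)
  if (is.null(labels)) labels <- paste0("c", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    abort_geomstate("RDM must be symmetric", "invalid_rdm_error")
  if (max(abs(diag(d))) > 1e-12)
    abort_geomstate("RDM diagonal must be zero", "invalid_rdm_error")
  structure(list(labels = labels, distances = d), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("rdm over %d conditions\n", length(x$labels)))
  print(round(x$distances, 3))
  invisible(x)
}

#' 2D goal model RDM
#'
#' Distances count mismatches over the two goal dimensions: 0 for the
#' same goal, 0.5 when exactly one of size/color direction matches, 1
#' when neither does (the normalized Hamming distance over the 2 binary
#' goal dimensions).
#'
#' @param goals character vector of goal ids \code{<size>_<color>}
#'   (default: the four goals in polygon order).
#' @return an \code{rdm}.
#' @export
model_rdm_2d <- function(goals = condition_order("goal_square")) {
  parts <- strsplit(goals, "_", fixed = TRUE)
  if (any(lengths(parts) != 2))
    abort_geomstate("goals must be '<size>_<color>' pairs", "invalid_label_error")
  sz <- vapply(parts, `[`, "", 1); cl <- vapply(parts, `[`, "", 2)
  d <- 0.5 * (outer(sz, sz, "!=") + outer(cl, cl, "!="))
  rdm(d, goals)
}

#' Conjunctive model RDM
#'
#' All goals equidistant: distance 1 between different conditions, 0
#' within. Encodes goal identity with no factorized 2D structure.
#'
#' @param goals character vector of goal ids.
#' @return an \code{rdm}.
#' @export
model_rdm_conjunctive <- function(goals = condition_order("goal_square")) {
  if (length(goals) < 2)
    abort_geomstate("need at least 2 goals", "invalid_label_error")
  d <- 1 - diag(length(goals))
  rdm(d, goals)
}

#' Expand a goal-level model RDM to finer conditions
#'
#' When data conditions are goal x stimulus cells, the model distance
#' between two cells is the model distance between their goals.
#'
#' @param model a goal-level \code{rdm}.
#' @param goal_of named character vector mapping condition id -> goal id.
#' @return an \code{rdm} over the conditions.
#' @export
expand_model_rdm <- function(model, goal_of) {
  g <- goal_of[!is.na(goal_of)]
  d <- model$distances[g, g, drop = FALSE]
  rdm(unname(d), names(g))
}

#' Cross-validated data RDM
#'
#' Trials are partitioned into stratified folds; for every condition
#' pair the correlation distance (1 - Pearson r) is computed between
#' condition means estimated on disjoint folds and averaged over all
#' ordered disjoint fold pairs, which makes the matrix exactly symmetric.
#' Channels are standardized (z-scored across trials) before averaging.
#' Cross-validation makes the distance an unbiased but possibly negative
#' estimator; negative values are retained.
#'
#' @param epochs an \code{epoch_array} or trials x channels matrix.
#' @param labels per-trial condition factor (NA trials dropped).
#' @param folds number of folds (default 4).
#' @param window \code{c(start, end)} ms window when \code{epochs} is an
#'   epoch array.
#' @param standardize z-score each channel across trials before averaging
#'   (default TRUE). Note that standardization removes any pattern shared
#'   by all trials, so fully condition-invariant structure does not lower
#'   the distances; disable it to compare raw patterns.
#' @param seed integer seed for the fold assignment.
#' @return an \code{rdm} (with possibly negative off-diagonal entries,
#'   stored with a zero diagonal).
#' @export
data_rdm_crossval <- function(epochs, labels, folds = 4L, window = NULL,
                              standardize = TRUE, seed = 1L) {
  m <- if (inherits(epochs, "epoch_array")) {
    sel <- epochs$times >= window[1] & epochs$times < window[2]
    apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  } else as.matrix(epochs)
  labels <- as.factor(labels)
  keep <- !is.na(labels)
  m <- m[keep, , drop = FALSE]; labels <- droplevels(labels[keep])
  counts <- table(labels)
  if (any(counts < folds))
    abort_geomstate("every condition needs at least `folds` trials",
                    "fold_coverage_error")
  if (standardize) m <- zscore_cols(m)$x
  lev <- levels(labels)
  fold_id <- with_seed(split_seed(seed, 171L), {
    f <- integer(nrow(m))
    for (l in lev) {
      ii <- which(labels == l)
      f[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
    f
  })
  # per-fold condition means: list of folds -> conditions x channels
  fm <- lapply(seq_len(folds), function(f) {
    ii <- fold_id == f
    rowsum(m[ii, , drop = FALSE], labels[ii]) /
      as.vector(table(labels[ii]))
  })
  k <- length(lev)
  d <- matrix(0, k, k)
  npairs <- 0L
  for (a in seq_len(folds)) for (b in seq_len(folds)) {
    if (a == b) next
    ca <- fm[[a]][lev, , drop = FALSE]
    cb <- fm[[b]][lev, , drop = FALSE]
    d <- d + (1 - stats::cor(t(ca), t(cb)))
    npairs <- npairs + 1L
  }
  d <- d / npairs
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rdm(d, lev)
}

# lower-triangle vectorization in a fixed label order
#' @keywords internal
rdm_vec <- function(x, labels = NULL) {
  d <- x$distances
  if (!is.null(labels)) d <- d[labels, labels]
  d[lower.tri(d)]
}

#' Compare a data RDM with model RDMs
#'
#' Spearman rank correlation between the lower-triangle vectors of the
#' data RDM and each model RDM; the partial variant partials each model
#' on all the others (competitive comparison), computed on average ranks
#' via the inverse correlation matrix.
#'
#' @param data_rdm an \code{rdm}.
#' @param model_rdms named list of model \code{rdm}s on the same labels.
#' @param metric \code{"spearman"} or \code{"partial_spearman"}.
#' @return named numeric vector, one statistic per model (NA for models
#'   with a constant distance vector, which are flagged by warning).
#' @export
rsa_compare <- function(data_rdm, model_rdms,
                        metric = c("spearman", "partial_spearman")) {
  metric <- match.arg(metric)
  if (inherits(model_rdms, "rdm")) model_rdms <- list(model = model_rdms)
  labs <- data_rdm$labels
  for (m in model_rdms)
    if (!setequal(m$labels, labs))
      abort_geomstate("model and data RDM label sets differ",
                      "invalid_label_error")
  dv <- rdm_vec(data_rdm)
  mv <- lapply(model_rdms, rdm_vec, labels = labs)
  const <- vapply(mv, function(v) stats::sd(v) == 0, TRUE)
  if (any(const))
    warning(sprintf("constant model vector(s): %s",
                    paste(names(mv)[const], collapse = ", ")))
  if (metric == "spearman") {
    out <- vapply(seq_along(mv), function(i) {
      if (const[i]) return(NA_real_)
      stats::cor(dv, mv[[i]], method = "spearman")
    }, 0)
  } else {
    if (length(mv) < 2)
      abort_geomstate("partial metric needs at least 2 models",
                      "invalid_parameter_error")
    keep <- which(!const)
    rk <- cbind(rank(dv), vapply(mv[keep], rank, numeric(length(dv))))
    cm <- stats::cor(rk)
    # a tiny ridge keeps the inversion defined when the data vector is an
    # exact copy of one model (partial correlation degenerates there)
    om <- tryCatch(solve(cm),
                   error = function(e) solve(cm + diag(1e-10, nrow(cm))))
    pc <- -om[1, -1] / sqrt(om[1, 1] * diag(om)[-1])
    out <- rep(NA_real_, length(mv))
    out[keep] <- pc
  }
  names(out) <- names(mv)
  out
}

#' Time-resolved RSA
#'
#' Computes a cross-validated data RDM per window and compares it with
#' the supplied models. Pointwise significance of the partial metric is
#' assessed per window independently elsewhere; this function returns the
#' statistics only.
#'
#' @inheritParams data_rdm_crossval
#' @param model_rdms named list of model \code{rdm}s.
#' @param metric comparison metric, see [rsa_compare()].
#' @param window_ms window length in ms.
#' @return matrix n_windows x n_models of statistics, with window centers
#'   as an attribute.
#' @export
rsa_timecourse <- function(epochs, labels, model_rdms,
                           metric = "spearman", folds = 4L, window_ms = 80,
                           seed = 1L) {
  windows <- window_partition(min(epochs$times),
                              max(epochs$times) + 1000 / epochs$sfreq, window_ms)
  out <- t(vapply(seq_len(nrow(windows)), function(w) {
    dr <- data_rdm_crossval(epochs, labels, folds = folds,
                            window = c(windows$start[w], windows$end[w]),
                            seed = split_seed(seed, w))
    rsa_compare(dr, model_rdms, metric = metric)
  }, numeric(length(model_rdms))))
  colnames(out) <- names(model_rdms)
  attr(out, "window_centers") <- windows$center
  out
}
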