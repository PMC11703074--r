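#' Fixed condition-order conventions
#'
#' Polygon vertices are always connected in a fixed, design-derived order,
#' never an order inferred from the data. For the goal square the walk is
#' bigger_redder - bigger_greener - smaller_greener - smaller_redder; for
#' the stimulus hexagon (3 sizes x 2 colors after dropping the middle color
#' bin) it is the perimeter walk of the grid, the only order in which
#' grid-adjacent conditions are polygon-adjacent.
#'
#' @param order_label one of \code{"goal_square"}, \code{"stimulus_hex"},
#'   \code{"stimulus_grid"}, \code{"motor_square"}.
#' @return character vector of condition ids in polygon order.
#' @export
condition_order <- function(order_label) {
  switch(order_label,
    goal_square = c("bigger_redder", "bigger_greener",
                    "smaller_greener", "smaller_redder"),
    motor_square = c("bigger_redder", "bigger_greener",
                     "smaller_greener", "smaller_redder"),
    stimulus_hex = c("s1_c1", "s2_c1", "s3_c1", "s3_c3", "s2_c3", "s1_c3"),
    stimulus_grid = as.vector(outer(1:3, 1:3,
                                    function(s, c) paste0("s", s, "_c", c))),
    abort_geomstate(sprintf("unknown order label '%s'", order_label),
                    "configuration_error")
  )
}

#' Condition-averaged channel matrix
#'
#' Averages the signal over a time window, then over trials within each
#' condition, yielding the n_conditions x n_channels matrix on which the
#' subspace is fit. Row order follows the level order of \code{labels}
#' (use [condition_order()] levels so downstream polygons are ordered by
#' convention).
#'
#' @param x an \code{epoch_array} (see [generate_epochs()]) or a numeric
#'   matrix of trials x channels (already window-averaged).
#' @param labels factor of condition labels, one per trial; its levels
#'   define row order.
#' @param window \code{c(start, end)} in ms (epoch time), used when
#'   \code{x} is an epoch array. Samples with \code{start <= t < end}
#'   are averaged.
#' @return matrix n_conditions x n_channels with condition ids as rownames.
#' @export
condition_average <- function(x, labels, window = NULL) {
  labels <- as.factor(labels)
  if (inherits(x, "epoch_array")) {
    if (is.null(window))
      abort_geomstate("window is required for epoch arrays", "invalid_parameter_error")
    sel <- x$times >= window[1] & x$times < window[2]
    if (!any(sel))
      abort_geomstate("window lies outside the epoch", "invalid_parameter_error")
    m <- apply(x$data[, , sel, drop = FALSE], c(1, 2), mean)
    colnames(m) <- x$channel_names
  } else {
    m <- as.matrix(x)
  }
  if (length(labels) != nrow(m))
    abort_geomstate("one label per trial required", "invalid_parameter_error")
  keep <- !is.na(labels)
  m <- m[keep, , drop = FALSE]; labels <- labels[keep]
  counts <- table(labels)
  if (any(counts == 0))
    abort_geomstate(sprintf("conditions with no trials: %s",
                            paste(names(counts)[counts == 0], collapse = ", ")),
                    "missing_condition_error")
  out <- rowsum(m, labels) / as.vector(counts)
  out[levels(labels), , drop = FALSE]
}

#' Fit the 2D condition subspace by PCA
#'
#' Each column (channel) of the condition matrix is standardized
#' independently (z-score across conditions; zero-variance channels are
#' zeroed, keeping channel indexing stable), then the top two principal
#' components of the standardized matrix are taken. Scores are projections
#' onto the unit-norm components without whitening, so the axes keep their
#' natural standard deviations.
#'
#' @param m condition matrix (n_conditions x n_channels), n_conditions >= 3.
#' @return object of class \code{subspace} with \code{column_means},
#'   \code{column_sds}, \code{components} (2 x n_channels, orthonormal
#'   rows) and \code{scores} (the fitted projections).
#' @export
fit_subspace <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3)
    abort_geomstate("need at least 3 conditions to fit a 2D subspace",
                    "degenerate_input_error")
  z <- zscore_cols(m)
  sv <- svd(z$x, nu = 0, nv = 2)
  comp <- t(sv$v)
  if (nrow(comp) < 2)  # fewer channels than 2: pad with zero loading row
    comp <- rbind(comp, matrix(0, 2 - nrow(comp), ncol(m)))
  structure(list(column_means = z$mu, column_sds = z$sd,
                 components = comp,
                 scores = z$x %*% t(comp),
                 channel_ids = colnames(m)),
            class = "subspace")
}

#' Project a condition matrix into a fitted subspace
#'
#' Standardization statistics are always those of the fitting matrix, so
#' held-out data (e.g., trial-split condition means) are projected into
#' the same space as the whole-data fit.
#'
#' @param subspace a [fit_subspace()] result.
#' @param m condition matrix with the same channels as the fit.
#' @return n_conditions x 2 matrix of coordinates (rownames preserved).
#' @export
project_conditions <- function(subspace, m) {
  m <- as.matrix(m)
  if (ncol(m) != length(subspace$column_means))
    abort_geomstate("channel set does not match the fitted subspace",
                    "incompatible_space_error")
  if (!is.null(subspace$channel_ids) && !is.null(colnames(m)) &&
      !identical(colnames(m), subspace$channel_ids))
    abort_geomstate("channel names do not match the fitted subspace",
                    "incompatible_space_error")
  z <- zscore_cols(m, mu = subspace$column_means, sd = subspace$column_sds)
  z$x %*% t(subspace$components)
}

#' Order projected coordinates into a condition polygon
#'
#' @param coords n x 2 coordinate matrix with condition ids as rownames
#'   (or assumed already in order when unnamed and \code{order_label =
#'   "custom"}).
#' @param order_label a [condition_order()] label or \code{"custom"}.
#' @return object of class \code{polygon_coords}.
#' @export
polygon_from <- function(coords, order_label = "goal_square") {
  coords <- as.matrix(coords)
  if (order_label != "custom") {
    ord <- condition_order(order_label)
    if (is.null(rownames(coords))) {
      if (nrow(coords) != length(ord))
        abort_geomstate("coordinate count does not match the condition order",
                        "configuration_error")
      rownames(coords) <- ord
    }
    if (!all(ord %in% rownames(coords)))
      abort_geomstate("coordinates are missing conditions of the requested order",
                      "configuration_error")
    coords <- coords[ord, , drop = FALSE]
  }
  if (nrow(coords) < 3)
    abort_geomstate("a polygon needs at least 3 vertices", "invalid_polygon_error")
  structure(list(vertices = coords, order_label = order_label),
            class = "polygon_coords")
}

# fast scalar circularity of an ordered vertex matrix
#' @keywords internal
circ_value <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  a <- 0.5 * abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]))
  p <- sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
  if (p == 0) return(0)
  4 * pi * a / p^2
}

#' Circularity index of a condition polygon
#'
#' \code{C = 4 * pi * Area / Perimeter^2}, where Area is the absolute
#' shoelace area of the fixed vertex cycle and Perimeter the sum of
#' consecutive edge lengths. A circle attains C = 1; a square pi/4
#' (about 0.78), which is also the maximum over quadrilaterals; collapsed
#' or self-intersecting cycles score near 0. If the perimeter is zero
#' (all vertices coincide) C is defined as 0.
#'
#' @param polygon a [polygon_from()] result, or a plain n x 2 matrix of
#'   ordered vertices.
#' @return object of class \code{circularity} with fields \code{C},
#'   \code{area}, \code{perimeter}.
#' @export
circularity <- function(polygon) {
  v <- if (inherits(polygon, "polygon_coords")) polygon$vertices else as.matrix(polygon)
  if (nrow(v) < 3 || ncol(v) != 2)
    abort_geomstate("circularity needs >= 3 ordered 2D vertices",
                    "invalid_polygon_error")
  n <- nrow(v)
  j <- c(2:n, 1L)
  area <- 0.5 * abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]))
  per <- sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
  C <- if (per == 0) 0 else 4 * pi * area / per^2
  structure(list(C = C, area = area, perimeter = per), class = "circularity")
}

#' @export
print.circularity <- function(x, ...) {
  cat(sprintf("circularity C = %.4f (area %.4g, perimeter %.4g)\n",
              x$C, x$area, x$perimeter))
  invisible(x)
}

# condition matrix -> circularity through the full standardize/PCA/project
# path, via the 4x4 (k x k) Gram shortcut: after column standardization the
# PCA scores equal sqrt(lambda_i) * u_i of the Gram matrix, which is all the
# polygon needs. Used by the resampling engines; equivalent to
# fit_subspace() + project_conditions() (tested).
#' @keywords internal
condmat_circularity <- function(m) {
  z <- zscore_cols(m)$x
  g <- tcrossprod(z)
  e <- eigen(g, symmetric = TRUE)
  s <- sqrt(pmax(e$values[1:2], 0))
  v <- e$vectors[, 1:2, drop = FALSE] * rep(s, each = nrow(g))
  circ_value(v)
}

#' Group-concatenated subspace visualization helper
#'
#' Concatenates per-subject condition matrices horizontally (subjects'
#' channels side by side) and fits a single subspace, for plotting
#' group-level geometry. Provided as a convenience visualization only;
#' it is not part of the tested inference path.
#'
#' @param mats list of condition matrices with identical row order.
#' @return the projected coordinates of the concatenated matrix.
#' @export
group_concat_projection <- function(mats) {
  m <- do.call(cbind, mats)
  fit_subspace(m)$scores
}
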