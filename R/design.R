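#' Task design specification
#'
#' Describes the counterbalanced working-memory manipulation design:
#' four goals (the cross of two binary goal dimensions, size and color)
#' by a 3 x 3 grid of stimulus feature bins, with a fixed number of
#' repetitions per cell spread over blocks. The default reproduces the
#' 648-trial session (4 goals x 9 stimulus cells x 18 repetitions in
#' 12 blocks).
#'
#' @param n_goals number of goals (the 2 x 2 goal cross), default 4.
#' @param size_bins number of stimulus size bins, default 3.
#' @param color_bins number of stimulus color bins, default 3.
#' @param reps_per_cell repetitions of every goal x stimulus cell, default 18.
#' @param n_blocks number of blocks the trials are divided into, default 12.
#' @return an object of class \code{design_spec}.
#' @export
design_spec <- function(n_goals = 4L, size_bins = 3L, color_bins = 3L,
                        reps_per_cell = 18L, n_blocks = 12L) {
  vals <- c(n_goals, size_bins, color_bins, reps_per_cell, n_blocks)
  if (any(!is.finite(vals)) || any(vals < 1) || any(vals != round(vals)))
    abort_geomstate("all design counts must be positive integers",
                    "invalid_spec_error")
  if (n_goals != 4L)
    abort_geomstate("the goal space is the cross of 2 binary dimensions; n_goals must be 4",
                    "invalid_spec_error")
  structure(list(n_goals = as.integer(n_goals),
                 size_bins = as.integer(size_bins),
                 color_bins = as.integer(color_bins),
                 reps_per_cell = as.integer(reps_per_cell),
                 n_blocks = as.integer(n_blocks)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  n <- x$n_goals * x$size_bins * x$color_bins * x$reps_per_cell
  cat(sprintf("design_spec: %d goals x %dx%d stimuli x %d reps = %d trials in %d blocks\n",
              x$n_goals, x$size_bins, x$color_bins, x$reps_per_cell, n, x$n_blocks))
  invisible(x)
}

# stimulus feature bin centers (size: fraction of screen height; color: steps
# on the 120-step green-red ladder) and the learned adjustment magnitudes
.size_bin_centers <- c(0.17, 0.22, 0.27)
.color_bin_centers <- c(34, 58, 82)
.size_adjust_frac <- 0.24   # +-24% of the original size
.color_adjust_steps <- 26   # +-26 color steps

#' Generate a counterbalanced trial table
#'
#' Every (goal, size bin, color bin) cell occurs exactly
#' \code{reps_per_cell} times; trial order is a seeded permutation. Goals
#' are the cross of \code{goal_size} (bigger/smaller) and \code{goal_color}
#' (redder/greener). Each trial also carries continuous stimulus feature
#' values (bin center plus a small uniform jitter), the random starting
#' values of the response object, and the correct target values implied by
#' the cued goal; response columns are initialized to the correct answer
#' and are overwritten by [generate_behavior()].
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a \code{data.frame} of class \code{trial_table}.
#' @seealso [generate_behavior()], [goal_labels()]
#' @export
generate_design <- function(spec = design_spec(), seed = 1L) {
  if (!inherits(spec, "design_spec")) spec <- do.call(design_spec, as.list(spec))
  n <- spec$n_goals * spec$size_bins * spec$color_bins * spec$reps_per_cell
  cells <- expand.grid(goal_size = c("bigger", "smaller"),
                       goal_color = c("redder", "greener"),
                       size_bin = seq_len(spec$size_bins),
                       color_bin = seq_len(spec$color_bins),
                       rep = seq_len(spec$reps_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- with_seed(split_seed(seed, 11L), {
    ord <- sample.int(nrow(cells))
    d <- cells[ord, c("goal_size", "goal_color", "size_bin", "color_bin")]
    rownames(d) <- NULL
    d$trial_id <- seq_len(nrow(d))
    d$block <- ceiling(d$trial_id / ceiling(nrow(d) / spec$n_blocks))
    # continuous stimulus values: bin center +- small jitter (size +-0.01
    # screen height, color +-2 steps), as in the binned stimulus ladder
    d$size_value <- .size_bin_centers[pmin(d$size_bin, 3L)] +
      stats::runif(nrow(d), -0.01, 0.01)
    d$color_value <- .color_bin_centers[pmin(d$color_bin, 3L)] +
      stats::runif(nrow(d), -2, 2)
    sdir <- ifelse(d$goal_size == "bigger", 1, -1)
    cdir <- ifelse(d$goal_color == "redder", 1, -1)
    d$size_target <- d$size_value * (1 + .size_adjust_frac * sdir)
    d$color_target <- d$color_value + .color_adjust_steps * cdir
    # response object starts at a random size/color; symmetric about the
    # target, so the adjustment direction is decoupled from the cued goal
    d$size_start <- d$size_target * stats::runif(nrow(d), 0.6, 1.4)
    d$color_start <- d$color_target + stats::runif(nrow(d), -30, 30)
    d$response_size <- d$size_target
    d$response_color <- d$color_target
    d$size_error <- 0
    d$color_error <- 0
    d$response_size_bin <- d$size_bin
    d$response_color_bin <- d$color_bin
    d
  })
  cols <- c("trial_id", "block", "goal_size", "goal_color", "size_bin",
            "color_bin", "response_size_bin", "response_color_bin",
            "size_error", "color_error", "size_value", "color_value",
            "size_start", "color_start", "size_target", "color_target",
            "response_size", "response_color")
  tab <- tab[, cols]
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Goal labels of a trial table
#'
#' The four goal conditions in the fixed polygon-order convention:
#' bigger_redder, bigger_greener, smaller_greener, smaller_redder
#' (the perimeter walk of the 2 x 2 goal square).
#'
#' @param trials a trial table.
#' @return a factor with the four goal levels in polygon order.
#' @export
goal_labels <- function(trials) {
  factor(paste(trials$goal_size, trials$goal_color, sep = "_"),
         levels = condition_order("goal_square"))
}

#' Stimulus labels of a trial table
#'
#' @param trials a trial table.
#' @param drop_middle_color drop the middle color bin, leaving the 6
#'   conditions of the stimulus hexagon (default TRUE). Trials in the
#'   dropped bin get \code{NA}.
#' @param use_response label by responded rather than presented feature bins.
#' @return a factor of stimulus conditions \code{s<size>_c<color>}.
#' @export
stimulus_labels <- function(trials, drop_middle_color = TRUE,
                            use_response = FALSE) {
  sb <- if (use_response) trials$response_size_bin else trials$size_bin
  cb <- if (use_response) trials$response_color_bin else trials$color_bin
  lab <- paste0("s", sb, "_c", cb)
  lev <- if (drop_middle_color) condition_order("stimulus_hex") else
    condition_order("stimulus_grid")
  if (drop_middle_color) lab[cb == 2L] <- NA
  factor(lab, levels = lev)
}

#' Color ladder specification and usable step count
#'
#' The color manipulation produces \code{n_raw_variants} color-shifted
#' renderings of a stimulus, of which the \code{n_discarded_extremes}
#' most extreme (uniformly red or green, hence contrast-free) are
#' discarded. The default (150, 30) leaves 120 usable steps.
#'
#' @param n_raw_variants raw color variants rendered (default 150).
#' @param n_discarded_extremes extreme variants discarded (default 30).
#' @return object of class \code{color_space_spec}.
#' @export
color_space_spec <- function(n_raw_variants = 150L, n_discarded_extremes = 30L) {
  if (n_raw_variants < 1 || n_discarded_extremes < 0 ||
      n_discarded_extremes >= n_raw_variants)
    abort_geomstate("discarded extremes must be fewer than raw variants",
                    "invalid_spec_error")
  structure(list(n_raw_variants = as.integer(n_raw_variants),
                 n_discarded_extremes = as.integer(n_discarded_extremes)),
            class = "color_space_spec")
}

#' @rdname color_space_spec
#' @param spec a \code{color_space_spec}.
#' @export
color_space_steps <- function(spec = color_space_spec()) {
  spec$n_raw_variants - spec$n_discarded_extremes
}
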