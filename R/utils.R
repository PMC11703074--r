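#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Sub-streams (design, epochs, behavior, permutations, ...) use seeds
#' derived deterministically from the master seed and a small integer key,
#' so that stages can be re-run independently yet reproducibly.
#'
#' @param seed master integer seed.
#' @param key non-negative integer identifying the stream.
#' @return an integer seed < 2^31 suitable for [set.seed()].
#' @export
split_seed <- function(seed, key = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(key))
  # Weyl-style mixing; kept in double precision, reduced mod 2^31 - 1
  m <- 2147483647
  x <- (abs(seed) %% m)
  x <- (x * 48271 + 1 + (key %% m) * 69621) %% m
  as.integer(x)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# column z-scores across rows; columns with zero variance are set to 0
#' @keywords internal
zscore_cols <- function(x, mu = NULL, sd = NULL) {
  if (is.null(mu)) mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  if (is.null(sd)) sd <- sqrt(colSums(xc^2) / max(1L, nrow(x) - 1L))
  keep <- sd > 0
  xs <- xc
  xs[, keep] <- sweep(xc[, keep, drop = FALSE], 2L, sd[keep], "/")
  xs[, !keep] <- 0
  list(x = xs, mu = mu, sd = sd)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_geomstate <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "geomstate_error")))
}
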