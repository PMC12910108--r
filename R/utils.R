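#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median rnorm rpois runif rexp sd coef fft lm nls resid
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a base seed and a stage counter
#'
#' Deterministic child-seed derivation so pipeline stages can be rerun
#' independently under one top-level seed. Linear congruential mix, kept
#' below 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param seed Base integer seed.
#' @param index Stage counter (any non-negative integer).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + 7919 * (index + 1)) %% m)
}

# Frame-averaged means of a piecewise-constant function.
#
# `breaks` are segment start times (first must be 0), `values` the level on
# [breaks[i], breaks[i + 1]); the last level extends to the end of the movie.
# Returns the mean level over each of `n_frames` exposures of length `dt`,
# i.e. the occupancy-weighted intensity a camera integrating over the
# exposure would record.
piecewise_frame_means <- function(breaks, values, n_frames, dt) {
  stopifnot(length(breaks) == length(values), breaks[1] <= 0)
  edges <- seq(0, n_frames * dt, by = dt)
  # cumulative integral of the level function at each frame edge
  seg_len <- diff(c(breaks, Inf))
  cum <- c(0, cumsum(utils::head(seg_len, -1) * utils::head(values, -1)))
  idx <- findInterval(edges, breaks)
  ci <- cum[idx] + (edges - breaks[idx]) * values[idx]
  diff(ci) / dt
}

# Maximal runs of TRUE allowing interior gaps shorter than `gap_frames`
# FALSE frames. Returns a data.frame of start/end indices (1-based,
# inclusive), end >= start. Gaps of gap_frames or more separate runs.
runs_with_gaps <- function(flag, gap_frames) {
  n <- length(flag)
  if (n == 0L || !any(flag)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # absorb short interior FALSE gaps
  if (gap_frames > 1L) {
    gap <- !r$values & r$lengths < gap_frames &
      seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    keep <- keep | gap
  }
  rr <- rle(keep)
  e2 <- cumsum(rr$lengths)
  s2 <- e2 - rr$lengths + 1L
  ok <- rr$values
  data.frame(start = starts[s2[ok]], end = ends[e2[ok]])
}

stop_invalid <- function(msg) {
  abort(msg, class = "smkinetics_invalid")
}
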