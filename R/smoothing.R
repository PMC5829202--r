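#' Savitzky-Golay smoothing of a trajectory
#'
#' Replaces each coordinate series by its Savitzky-Golay local-polynomial
#' fit: within a sliding window of `window` frames a polynomial of degree
#' `polyorder` is least-squares fitted and evaluated at the window centre.
#' Interior frames use the standard symmetric filter; the first and last
#' half-windows are fitted on the shrinking set of available frames (no
#' padding), so no positions are fabricated outside the observation
#' interval. Smoothing is linear in the coordinates and therefore exactly
#' translation- and rotation-equivariant.
#'
#' @param traj a gap-free [trajectory()].
#' @param window odd window length in frames; default 15.
#' @param polyorder polynomial degree, must be `< window`; default 3, which
#'   preserves position, velocity and acceleration structure of the track.
#' @return the smoothed trajectory (`smoothed` flag set).
#' @export
smooth_trajectory <- function(traj, window = 15, polyorder = 3) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window > nf) stop("`window` exceeds the number of frames")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (anyNA(traj$positions)) {
    stop("trajectory has missing positions; run fill_gaps() first")
  }
  pos <- traj$positions
  for (i in seq_len(dim(pos)[2])) {
    for (d in 1:2) {
      pos[, i, d] <- sg_smooth_series(pos[, i, d], window, polyorder)
    }
  }
  trajectory(pos, fps = traj$fps, trial_id = traj$trial_id, ids = traj$ids,
             smoothed = TRUE)
}

# One series: symmetric SG filter in the interior, shrinking-window
# polynomial least squares at the ends.
sg_smooth_series <- function(x, window, polyorder) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  coef <- signal::sgolay(p = polyorder, n = window)[h + 1L, ]
  out <- stats::filter(x, coef, sides = 2)
  out <- as.numeric(out)
  for (t in seq_len(h)) {
    idx <- 1L:(t + h)
    out[t] <- shrunk_polyfit(idx, x[idx], t, polyorder)
    idx2 <- (n - t - h + 1L):n
    out[n - t + 1L] <- shrunk_polyfit(idx2, x[idx2], n - t + 1L, polyorder)
  }
  out
}

# Least-squares polynomial fit on the (possibly short) window, evaluated at
# frame t0. Degree shrinks with the window so the system stays determined.
shrunk_polyfit <- function(idx, y, t0, polyorder) {
  p <- min(polyorder, length(idx) - 1L)
  z <- idx - t0                       # centre for conditioning
  X <- outer(z, 0:p, `^`)
  fit <- stats::lm.fit(X, y)
  fit$coefficients[1L]
}
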