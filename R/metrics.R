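#' Per-frame group centroid
#'
#' The group centroid at a frame is the arithmetic mean position of all
#' members, so the member displacement vectors about it sum to zero.
#'
#' @param traj a gap-free [trajectory()].
#' @return numeric matrix `n_frames x 2`, mm.
#' @export
compute_centroid <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  cbind(rowMeans(traj$positions[, , 1, drop = FALSE]),
        rowMeans(traj$positions[, , 2, drop = FALSE]))
}

#' Per-frame individual swim speeds
#'
#' Speed of individual i at frame t is the one-frame displacement norm
#' scaled to cm/s: `||p_i(t+1) - p_i(t)|| * fps / 10`. The last frame
#' repeats the preceding value so the series has full length.
#'
#' @param traj a gap-free [trajectory()].
#' @return numeric matrix `n_frames x n_individuals`, cm/s.
#' @export
compute_speeds <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  nf <- dim(p)[1]
  dx <- p[-1, , 1, drop = FALSE] - p[-nf, , 1, drop = FALSE]
  dy <- p[-1, , 2, drop = FALSE] - p[-nf, , 2, drop = FALSE]
  sp <- sqrt(dx^2 + dy^2)[, , 1, drop = TRUE] * traj$fps / 10
  sp <- matrix(sp, nrow = nf - 1L)
  rbind(sp, sp[nf - 1L, , drop = FALSE])
}

#' Per-frame unit headings from displacement
#'
#' The heading of an individual is the direction of its one-frame
#' displacement, provided the step is at least `min_step` mm; for smaller
#' steps (tracking jitter around a near-stationary fish) the last valid
#' heading is carried forward. Headings are undefined (`NA`) before the
#' first valid step.
#'
#' @param traj a gap-free [trajectory()].
#' @param min_step minimum displacement (mm) for a step to define a
#'   heading; default 0.2.
#' @return numeric array `n_frames x n_individuals x 2` of unit vectors.
#' @export
compute_headings <- function(traj, min_step = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  nf <- dim(p)[1]; ni <- dim(p)[2]
  out <- array(NA_real_, dim = c(nf, ni, 2))
  for (i in seq_len(ni)) {
    dx <- diff(p[, i, 1]); dy <- diff(p[, i, 2])
    len <- sqrt(dx^2 + dy^2)
    ok <- which(len >= min_step)
    if (!length(ok)) next
    ux <- dx[ok] / len[ok]; uy <- dy[ok] / len[ok]
    # frame t takes the most recent valid step at or before t; the step
    # t -> t+1 defines the heading at frame t
    take <- findInterval(seq_len(nf), ok)
    def <- take > 0L
    out[def, i, 1] <- ux[take[def]]
    out[def, i, 2] <- uy[take[def]]
  }
  out
}

#' Per-frame polarization order parameter
#'
#' Polarization is the magnitude of the mean unit heading over members with
#' a defined heading: 1 when all are aligned, 0 when headings cancel.
#' Undefined (`NA`) when fewer than two headings are defined.
#'
#' @param headings array from [compute_headings()].
#' @return numeric vector of length `n_frames`, in `[0, 1]` or `NA`.
#' @export
compute_polarization <- function(headings) {
  stopifnot(is.array(headings), length(dim(headings)) == 3L)
  ux <- matrix(headings[, , 1], nrow = dim(headings)[1])
  uy <- matrix(headings[, , 2], nrow = dim(headings)[1])
  n_def <- rowSums(!is.na(ux))
  sx <- rowSums(ux, na.rm = TRUE)
  sy <- rowSums(uy, na.rm = TRUE)
  out <- sqrt(sx^2 + sy^2) / n_def
  out[n_def < 2L] <- NA_real_
  out
}

#' Per-frame distance to the group centroid (cohesion)
#'
#' @param traj a gap-free [trajectory()].
#' @return numeric matrix `n_frames x n_individuals`, cm.
#' @export
compute_cohesion <- function(traj) {
  cen <- compute_centroid(traj)
  p <- traj$positions
  dx <- p[, , 1, drop = TRUE] - cen[, 1]
  dy <- p[, , 2, drop = TRUE] - cen[, 2]
  matrix(sqrt(dx^2 + dy^2) / 10, nrow = dim(p)[1])
}

centroid_velocity <- function(traj) {
  cen <- compute_centroid(traj)
  nf <- nrow(cen)
  v <- (cen[-1, , drop = FALSE] - cen[-nf, , drop = FALSE]) * traj$fps
  rbind(v, v[nf - 1L, , drop = FALSE])  # mm/s; last frame repeats
}

#' Per-frame front-of-centroid indicator (leadership)
#'
#' An individual is "in front" at a frame when its displacement from the
#' centroid has a strictly positive projection on the centroid velocity.
#' When the centroid moves slower than `min_centroid_speed` the group has
#' no meaningful front and the indicator is undefined (`NA`) for every
#' member at that frame.
#'
#' @param traj a gap-free [trajectory()].
#' @param min_centroid_speed minimum centroid speed (cm/s) for a front to
#'   be defined; default 0.5.
#' @return logical matrix `n_frames x n_individuals` with `NA` rows for
#'   near-stationary frames.
#' @export
compute_in_front <- function(traj, min_centroid_speed = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  cen <- compute_centroid(traj)
  v <- centroid_velocity(traj)
  speed <- sqrt(rowSums(v^2)) / 10  # cm/s
  p <- traj$positions
  proj <- (p[, , 1, drop = TRUE] - cen[, 1]) * v[, 1] +
          (p[, , 2, drop = TRUE] - cen[, 2]) * v[, 2]
  out <- matrix(proj > 0, nrow = dim(p)[1])
  out[speed < min_centroid_speed, ] <- NA
  out
}

#' Population variance across group members
#'
#' Variance with divisor n (not n-1): the members observed are the whole
#' group, not a sample from one. Used for the leadership-structure measure,
#' the variance across members of their front-of-centroid proportions.
#'
#' @param x numeric vector.
#' @return population variance of `x`.
#' @examples
#' leadership_variance(c(1, 0.5, 0.5, 0.5, 0))  # 0.1
#' @export
leadership_variance <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Split a foraging trial at the food-depletion frame
#'
#' @param traj the trial's [trajectory()].
#' @param meta the trial's [trial_metadata()]; `depletion_frame` must be
#'   set and inside the trial.
#' @return list of two frame windows `pre` and `post`, each a half-open
#'   0-based interval `c(start, end)`.
#' @export
split_foraging_trial <- function(traj, meta) {
  stopifnot(inherits(traj, "trajectory"), inherits(meta, "trial_metadata"))
  dfr <- meta$depletion_frame
  if (is.na(dfr)) stop("metadata has no depletion_frame")
  nf <- n_frames(traj)
  if (dfr < 0 || dfr > nf) {
    stop(sprintf("depletion_frame %d outside trial of %d frames", dfr, nf))
  }
  list(pre = c(0L, as.integer(dfr)), post = c(as.integer(dfr), nf))
}

window_rows <- function(win, nf) {
  if (is.null(win)) win <- c(0L, nf)
  if (win[1] < 0 || win[2] > nf || win[2] <= win[1]) {
    stop(sprintf("empty or invalid frame window [%d, %d)", win[1], win[2]))
  }
  (win[1] + 1L):win[2]
}

#' Summarize one trial into the mixed-model response variables
#'
#' Computes, over the selected frame window, the per-individual responses
#' (median swim speed, mean distance to the group centroid, proportion of
#' defined frames spent in front of the centroid) and the group-level
#' responses (median polarization; leadership structure, the population
#' variance across members of the front proportions). When the metadata
#' carries a cover circle, cover-use statistics (mean number of fish out of
#' cover, proportion of frames with all fish out) are added.
#'
#' @param traj a smoothed, gap-free [trajectory()].
#' @param meta the trial's [trial_metadata()].
#' @param frame_window half-open 0-based `c(start, end)` frame interval, or
#'   `NULL` for the whole trial.
#' @param min_step passed to [compute_headings()].
#' @param min_centroid_speed passed to [compute_in_front()].
#' @return an object of class `"trial_metrics"`: list with data frames
#'   `individual` (one row per fish) and `group` (one row).
#' @export
summarize_trial <- function(traj, meta, frame_window = NULL,
                            min_step = 0.2, min_centroid_speed = 0.5) {
  stopifnot(inherits(traj, "trajectory"), inherits(meta, "trial_metadata"))
  nf <- n_frames(traj)
  rows <- window_rows(frame_window, nf)
  sp <- compute_speeds(traj)[rows, , drop = FALSE]
  coh <- compute_cohesion(traj)[rows, , drop = FALSE]
  hd <- compute_headings(traj, min_step = min_step)
  pol <- compute_polarization(hd)[rows]
  infr <- compute_in_front(traj, min_centroid_speed)[rows, , drop = FALSE]
  def <- !is.na(infr[, 1])
  if (!any(def)) {
    stop(sprintf("trial '%s': no frames with a defined group front",
                 traj$trial_id))
  }
  front_prop <- colMeans(infr[def, , drop = FALSE])
  ind <- data.frame(
    trial_id = traj$trial_id, group_id = meta$group_id,
    context = meta$context, trial_number = meta$trial_number,
    individual_id = traj$ids,
    median_speed = apply(sp, 2, stats::median),
    mean_centre_distance = colMeans(coh),
    front_proportion = front_prop,
    row.names = NULL)
  grp <- data.frame(
    trial_id = traj$trial_id, group_id = meta$group_id,
    context = meta$context, trial_number = meta$trial_number,
    median_polarization = stats::median(pol, na.rm = TRUE),
    leadership_variance = leadership_variance(front_prop),
    n_leadership_frames = sum(def),
    row.names = NULL)
  grp$mean_n_out_of_cover <- NA_real_
  grp$prop_all_out <- NA_real_
  if (!is.null(meta$cover)) {
    p <- traj$positions[rows, , , drop = FALSE]
    dx <- p[, , 1, drop = TRUE] - meta$cover$centre[1]
    dy <- p[, , 2, drop = TRUE] - meta$cover$centre[2]
    out_of_cover <- matrix(sqrt(dx^2 + dy^2) > meta$cover$radius,
                           nrow = length(rows))
    n_out <- rowSums(out_of_cover)
    grp$mean_n_out_of_cover <- mean(n_out)
    grp$prop_all_out <- mean(n_out == n_individuals(traj))
  }
  structure(list(individual = ind, group = grp), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  g <- x$group
  cat(sprintf(
    "<trial_metrics '%s'> median polarization %.3f, leadership var %.4f\n",
    g$trial_id, g$median_polarization, g$leadership_variance))
  print(x$individual[, c("individual_id", "median_speed",
                         "mean_centre_distance", "front_proportion")],
        row.names = FALSE)
  invisible(x)
}
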