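#' Trajectory container
#'
#' A trajectory holds the 2-D positions of every individual in one trial,
#' sampled at a fixed frame rate. Positions are stored as a numeric array
#' indexed `[frame, individual, coordinate]` in millimetres, with the arena
#' centre at the origin and y pointing up. Frames are 0-based externally
#' (file format, frame windows) and contiguous; missing observations are
#' `NA` until [fill_gaps()] is applied.
#'
#' @param positions numeric array `n_frames x n_individuals x 2`, in mm.
#'   `NA` marks a missing observation.
#' @param fps frames per second (Hz), must be positive. Default 24.
#' @param trial_id trial identifier.
#' @param ids character vector of individual identifiers, one per column of
#'   `positions`. Defaults to `"f1" ... "fn"`.
#' @param smoothed logical, whether the positions have been smoothed.
#' @return an object of class `"trajectory"`.
#' @seealso [fill_gaps()], [smooth_trajectory()], [read_trajectories()]
#' @examples
#' pos <- array(0, dim = c(10, 2, 2))
#' pos[, 1, 1] <- 0:9          # fish 1 swims +x at 1 mm/frame
#' pos[, 2, 1] <- 0:9 + 10
#' tr <- trajectory(pos, fps = 24, trial_id = "demo")
#' tr
#' @export
trajectory <- function(positions, fps = 24, trial_id = "trial",
                       ids = NULL, smoothed = FALSE) {
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[3] != 2L) {
    stop("`positions` must be an n_frames x n_individuals x 2 array")
  }
  n_frames <- dim(positions)[1]
  n_ind <- dim(positions)[2]
  if (n_frames < 2L) stop("a trajectory needs at least 2 frames")
  if (n_ind < 1L) stop("a trajectory needs at least 1 individual")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number")
  }
  if (is.null(ids)) ids <- paste0("f", seq_len(n_ind))
  if (length(ids) != n_ind) stop("`ids` length must match individuals")
  # x and y must be missing together: a half-observed point is malformed
  na_x <- is.na(positions[, , 1, drop = FALSE])
  na_y <- is.na(positions[, , 2, drop = FALSE])
  if (any(na_x != na_y)) stop("x and y must be NA together")
  structure(
    list(trial_id = as.character(trial_id), fps = fps,
         positions = positions, ids = as.character(ids),
         smoothed = isTRUE(smoothed)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$positions)
  n_na <- sum(is.na(x$positions[, , 1]))
  cat(sprintf(
    "<trajectory '%s'> %d frames x %d individuals @ %g fps (%.1f s)%s%s\n",
    x$trial_id, d[1], d[2], x$fps, d[1] / x$fps,
    if (x$smoothed) ", smoothed" else ", raw",
    if (n_na) sprintf(", %d missing", n_na) else ""))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]
n_individuals <- function(traj) dim(traj$positions)[2]

#' Trial metadata
#'
#' Describes the experimental setting of one trial: identity of the group,
#' context, arena geometry and, for foraging contexts, the food patches and
#' the frame at which the last food item was consumed. All geometry is in mm
#' with the arena centre at the origin.
#'
#' @param trial_id trial identifier matching the trajectory.
#' @param group_id group identifier.
#' @param context one of `"open"`, `"foraging"`, `"cover"`. (The four-level
#'   analysis factor open / foraging_pre / foraging_post / cover is derived
#'   downstream by splitting foraging trials at `depletion_frame`.)
#' @param trial_number trial number within the context (1-based).
#' @param arena list with `centre` (length-2, mm) and `radius` (mm).
#' @param food_patches data frame with columns `x`, `y`, `radius`, `n_items`
#'   (one row per patch), or `NULL`.
#' @param cover list with `centre` and `radius`, or `NULL`.
#' @param depletion_frame 0-based frame at which the last item was eaten.
#'   Required iff `context` involves food (`"foraging"` or `"cover"` with
#'   patches); `NA` allowed for cover trials where food is ancillary.
#' @param body_length_mm mean body length of the fish (mm), default 40.6.
#' @param fps frames per second, default 24.
#' @return an object of class `"trial_metadata"`.
#' @export
trial_metadata <- function(trial_id, group_id, context, trial_number = 1L,
                           arena = list(centre = c(0, 0), radius = 400),
                           food_patches = NULL, cover = NULL,
                           depletion_frame = NULL,
                           body_length_mm = 40.6, fps = 24) {
  context <- match.arg(context, c("open", "foraging", "cover"))
  if (body_length_mm <= 0) stop("`body_length_mm` must be positive")
  if (context == "foraging" &&
      (is.null(depletion_frame) || is.na(depletion_frame))) {
    stop("foraging trials require a `depletion_frame`")
  }
  if (context == "open" && !is.null(depletion_frame) &&
      !is.na(depletion_frame)) {
    stop("`depletion_frame` only applies to contexts with food")
  }
  if (!is.null(food_patches)) {
    food_patches <- as.data.frame(food_patches)
    stopifnot(all(c("x", "y", "radius", "n_items") %in% names(food_patches)))
  }
  structure(
    list(trial_id = as.character(trial_id), group_id = as.character(group_id),
         context = context, trial_number = as.integer(trial_number),
         arena = arena, food_patches = food_patches, cover = cover,
         depletion_frame = if (is.null(depletion_frame)) NA_integer_
                           else as.integer(depletion_frame),
         body_length_mm = body_length_mm, fps = fps),
    class = "trial_metadata")
}

#' @export
print.trial_metadata <- function(x, ...) {
  cat(sprintf("<trial_metadata '%s'> group %s, %s context, trial %d\n",
              x$trial_id, x$group_id, x$context, x$trial_number))
  invisible(x)
}

# ---- file formats -----------------------------------------------------------
# Trajectory CSV: '#'-prefixed header declaring units (mm|px), scale (mm per
# px) and fps, then columns trial_id, frame, fish_id, x, y. Metadata CSV: one
# row per trial; patch list encoded "x:y:radius:n_items" joined by ';'.

parse_header <- function(path) {
  out <- list(units = "mm", scale = 1, fps = 24)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    m <- regmatches(ln, regexec("^#\\s*(\\w+)\\s*[:=]\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- m[3]
      if (key %in% c("scale", "fps")) val <- as.numeric(val)
      out[[key]] <- val
    }
  }
  out
}

#' Read trajectories and trial metadata
#'
#' Reads a trajectory CSV (columns `trial_id, frame, fish_id, x, y`, with a
#' `#`-comment header declaring `units` (mm or px), `scale` (mm per px) and
#' `fps`) together with a metadata CSV, and returns one [trajectory()] per
#' trial joined to its [trial_metadata()]. Pixel coordinates are converted
#' to mm using the declared scale. Rows with empty `x`/`y` are explicit
#' missing markers; frames must be contiguous from 0 within each trial.
#'
#' @param path trajectory CSV path.
#' @param metadata_path metadata CSV path.
#' @return list with elements `trajectories` (named list of trajectory) and
#'   `metadata` (named list of trial_metadata), in matching order.
#' @export
read_trajectories <- function(path, metadata_path) {
  hdr <- parse_header(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trial_id", "frame", "fish_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  }
  if (identical(hdr$units, "px")) {
    df$x <- df$x * hdr$scale
    df$y <- df$y * hdr$scale
  }
  metas <- read_trial_metadata(metadata_path)
  trajs <- list()
  for (tid in unique(df$trial_id)) {
    sub <- df[df$trial_id == tid, ]
    if (is.null(metas[[tid]])) {
      stop(sprintf("trial '%s' has no metadata record", tid))
    }
    if (anyDuplicated(sub[c("frame", "fish_id")])) {
      dup <- sub[duplicated(sub[c("frame", "fish_id")]), ][1, ]
      stop(sprintf("trial '%s': duplicated row for frame %d, fish '%s'",
                   tid, dup$frame, dup$fish_id))
    }
    for (fid in unique(sub$fish_id)) {
      fr <- sub$frame[sub$fish_id == fid]
      if (any(diff(fr) <= 0)) {
        stop(sprintf("trial '%s', fish '%s': non-monotone frame index",
                     tid, fid))
      }
    }
    frames <- sort(unique(sub$frame))
    expect <- seq(0L, max(frames))
    if (!identical(as.integer(frames), expect)) {
      gap <- setdiff(expect, frames)[1]
      stop(sprintf("trial '%s': frame sequence has a gap at frame %d",
                   tid, gap))
    }
    ids <- unique(sub$fish_id)
    nf <- length(expect)
    pos <- array(NA_real_, dim = c(nf, length(ids), 2))
    fi <- sub$frame + 1L
    ii <- match(sub$fish_id, ids)
    pos[cbind(fi, ii, 1L)] <- sub$x
    pos[cbind(fi, ii, 2L)] <- sub$y
    trajs[[tid]] <- trajectory(pos, fps = hdr$fps, trial_id = tid, ids = ids)
  }
  list(trajectories = trajs, metadata = metas[names(trajs)])
}

#' Write trajectories to CSV
#'
#' Inverse of [read_trajectories()]; always writes mm coordinates.
#'
#' @param trajs a trajectory or list of trajectories.
#' @param path output CSV path.
#' @param digits numeric precision for coordinates. Default 6 significant
#'   decimal digits after rounding to 1e-6 mm.
#' @export
write_trajectories <- function(trajs, path, digits = 6) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  fps <- trajs[[1]]$fps
  rows <- lapply(trajs, function(tr) {
    nf <- n_frames(tr); ni <- n_individuals(tr)
    data.frame(
      trial_id = tr$trial_id,
      frame = rep(seq_len(nf) - 1L, times = ni),
      fish_id = rep(tr$ids, each = nf),
      x = round(as.vector(tr$positions[, , 1]), digits),
      y = round(as.vector(tr$positions[, , 2]), digits))
  })
  df <- do.call(rbind, rows)
  df <- df[order(match(df$trial_id, names(trajs)), df$frame), ]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# units: mm", "# scale: 1", paste0("# fps: ", fps)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_patches <- function(fp) {
  if (is.null(fp) || !nrow(fp)) return("")
  paste(sprintf("%g:%g:%g:%d", fp$x, fp$y, fp$radius, as.integer(fp$n_items)),
        collapse = ";")
}

parse_patches <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    data.frame(x = as.numeric(p[1]), y = as.numeric(p[2]),
               radius = as.numeric(p[3]), n_items = as.integer(p[4]))
  }))
}

#' Write trial metadata to CSV
#' @param metas a trial_metadata or list of them.
#' @param path output CSV path.
#' @export
write_trial_metadata <- function(metas, path) {
  if (inherits(metas, "trial_metadata")) metas <- list(metas)
  df <- do.call(rbind, lapply(metas, function(m) {
    data.frame(
      trial_id = m$trial_id, group_id = m$group_id, context = m$context,
      trial_number = m$trial_number,
      arena_x = m$arena$centre[1], arena_y = m$arena$centre[2],
      arena_radius = m$arena$radius,
      food_patches = fmt_patches(m$food_patches),
      cover = if (is.null(m$cover)) "" else
        sprintf("%g:%g:%g", m$cover$centre[1], m$cover$centre[2],
                m$cover$radius),
      depletion_frame = m$depletion_frame,
      body_length_mm = m$body_length_mm, fps = m$fps)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trial metadata from CSV
#' @param path metadata CSV path.
#' @return named list of [trial_metadata()] keyed by trial_id.
#' @export
read_trial_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(food_patches = "character",
                                       cover = "character"))
  out <- list()
  for (k in seq_len(nrow(df))) {
    r <- df[k, ]
    cov <- NULL
    if (!is.na(r$cover) && nzchar(r$cover)) {
      p <- as.numeric(strsplit(r$cover, ":", fixed = TRUE)[[1]])
      cov <- list(centre = p[1:2], radius = p[3])
    }
    out[[r$trial_id]] <- trial_metadata(
      trial_id = r$trial_id, group_id = r$group_id, context = r$context,
      trial_number = r$trial_number,
      arena = list(centre = c(r$arena_x, r$arena_y), radius = r$arena_radius),
      food_patches = parse_patches(r$food_patches), cover = cov,
      depletion_frame = if (is.na(r$depletion_frame)) NULL
                        else r$depletion_frame,
      body_length_mm = r$body_length_mm, fps = r$fps)
  }
  out
}

#' Fill gaps in a trajectory by linear interpolation
#'
#' Interior runs of missing positions are replaced by linear interpolation
#' between the flanking observed positions; leading and trailing gaps take
#' the nearest observed position. A run longer than `max_gap` frames is an
#' error: long occlusions should not be invented by interpolation.
#'
#' @param traj a [trajectory()].
#' @param max_gap maximum gap length, in frames, that may be interpolated.
#'   Default 15, matching the smoothing window.
#' @return a gap-free trajectory.
#' @export
fill_gaps <- function(traj, max_gap = 15) {
  stopifnot(inherits(traj, "trajectory"))
  pos <- traj$positions
  nf <- dim(pos)[1]
  for (i in seq_len(dim(pos)[2])) {
    miss <- is.na(pos[, i, 1])
    if (!any(miss)) next
    if (all(miss)) {
      stop(sprintf("individual '%s' has no observed positions", traj$ids[i]))
    }
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bad <- which(runs$values & runs$lengths > max_gap)
    if (length(bad)) {
      b <- bad[1]
      stop(sprintf(
        "individual '%s': gap of %d frames (frames %d-%d) exceeds max_gap=%d",
        traj$ids[i], runs$lengths[b], starts[b] - 1L, ends[b] - 1L, max_gap))
    }
    obs <- which(!miss)
    for (d in 1:2) {
      pos[, i, d] <- stats::approx(obs, pos[obs, i, d], xout = seq_len(nf),
                                   method = "linear", rule = 2)$y
    }
  }
  trajectory(pos, fps = traj$fps, trial_id = traj$trial_id, ids = traj$ids,
             smoothed = traj$smoothed)
}
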