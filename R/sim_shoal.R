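#' Configuration for the agent-based shoal simulator
#'
#' A zonal (metric-zone) schooling model: each agent is repelled from
#' neighbours inside the repulsion zone; otherwise it averages alignment
#' with neighbour headings (alignment zone) and attraction towards
#' neighbours (attraction zone), avoids the arena wall, and moves at its
#' preferred speed with von Mises heading noise. Context machinery adds
#' three food patches (agents are drawn to a detected patch, slow down
#' while food is present, and pause to handle an eaten item) and a central
#' cover circle (agents inside it may stop hiding under cover and resume
#' stochastically).
#'
#' Defaults mirror the study scenario: a circular 80 cm arena, groups of 5
#' fish of 40.6 mm released from a 10 cm central start cylinder, 24 fps,
#' three 5-item food patches in a triangle, a 15 cm central cover circle.
#'
#' @param context `"open"`, `"foraging"` or `"cover"`.
#' @param n_fish agents per group; default 5.
#' @param arena_radius arena radius, mm; default 400.
#' @param fps frames per second; default 24.
#' @param duration_s trial length, s. Defaults per context to the study
#'   protocol: open 1800, foraging 300, cover 600.
#' @param r_repulsion,r_alignment,r_attraction zone radii, mm
#'   (defaults 30, 120, 400; `0 < r_rep < r_align < r_attr`).
#' @param v_pref_mean population mean preferred speed, cm/s; default 3.25.
#' @param v_pref_group_sd group-level SD of preferred speed, cm/s;
#'   default 0.75.
#' @param v_pref_ind_sd individual-level SD, cm/s; default 0.05 (fish
#'   conform strongly in speed within a group).
#' @param heading_noise_sd von Mises heading noise SD per frame, rad;
#'   default 0.3.
#' @param max_turn maximum turn per frame towards the desired direction,
#'   rad; default 0.3 (about 7 rad/s at 24 fps). Limiting the turn rate
#'   keeps headings persistent, as real fish cannot reverse instantly.
#' @param patch_items food items per patch; default 5 (three patches).
#' @param patch_radius patch radius, mm; default 25 (5 cm lattice).
#' @param detection_radius distance at which a patch is noticed, mm;
#'   default 175.
#' @param feed_slowdown multiplicative speed factor while food remains;
#'   default 0.75.
#' @param post_depletion_speedup speed factor after depletion; default 1.3.
#' @param handling_time_s pause after eating an item, s; default 2.
#' @param cover_radius cover circle radius, mm; default 75.
#' @param p_enter_cover per-second probability of stopping under cover when
#'   inside the circle; default 0.4.
#' @param p_exit_cover per-second probability of resuming; default 0.15.
#' @param body_length_mm body length, mm; default 40.6.
#' @param start_radius release cylinder radius, mm; default 50.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(context = c("open", "foraging", "cover"),
                       n_fish = 5, arena_radius = 400, fps = 24,
                       duration_s = NULL,
                       r_repulsion = 30, r_alignment = 120,
                       r_attraction = 400,
                       v_pref_mean = 3.25, v_pref_group_sd = 0.5,
                       v_pref_ind_sd = 0.05, heading_noise_sd = 0.3,
                       max_turn = 0.3,
                       patch_items = 5, patch_radius = 25,
                       detection_radius = 175, feed_slowdown = 0.75,
                       post_depletion_speedup = 1.3, handling_time_s = 2,
                       cover_radius = 75, p_enter_cover = 0.4,
                       p_exit_cover = 0.15, body_length_mm = 40.6,
                       start_radius = 50) {
  context <- match.arg(context)
  if (is.null(duration_s)) {
    duration_s <- c(open = 1800, foraging = 300, cover = 600)[[context]]
  }
  stopifnot(0 < r_repulsion, r_repulsion < r_alignment,
            r_alignment < r_attraction,
            p_enter_cover >= 0, p_enter_cover <= 1,
            p_exit_cover >= 0, p_exit_cover <= 1,
            n_fish >= 1, duration_s * fps >= 2)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# triangular patch layout, centred at 2/3 arena radius
default_patches <- function(cfg) {
  ang <- pi / 2 + c(0, 2, 4) * pi / 3
  r <- 2 / 3 * cfg$arena_radius
  data.frame(x = r * cos(ang), y = r * sin(ang),
             radius = cfg$patch_radius, n_items = cfg$patch_items)
}

# vectorized von Mises sampler (Best & Fisher 1979), batch rejection
rvonmises <- function(n, kappa) {
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Simulate one trial of the zonal shoal model
#'
#' Runs the agent model described in [sim_config()] and returns the raw
#' trajectory together with trial metadata; for foraging/cover contexts the
#' metadata's `depletion_frame` is the logged frame at which the last food
#' item was eaten (`NA` if food survives the trial, which does not occur at
#' the defaults). Fully reproducible from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param group_trait group-level offset added to every agent's preferred
#'   speed, cm/s.
#' @param individual_traits per-agent offsets, cm/s (length `n_fish`).
#' @param seed integer seed.
#' @param trial_id,group_id,trial_number metadata fields.
#' @return list with `trajectory` and `metadata`.
#' @export
simulate_trial <- function(cfg, group_trait = 0,
                           individual_traits = rep(0, cfg$n_fish),
                           seed = 1, trial_id = "sim1", group_id = "g01",
                           trial_number = 1L) {
  stopifnot(inherits(cfg, "sim_config"),
            length(individual_traits) == cfg$n_fish)
  set.seed(seed)
  m <- cfg$n_fish
  nf <- as.integer(round(cfg$duration_s * cfg$fps))
  R <- cfg$arena_radius
  v_pref <- pmax(0.2, cfg$v_pref_mean + group_trait + individual_traits)
  step_len <- v_pref * 10 / cfg$fps           # mm per frame at full speed
  kappa <- 1 / cfg$heading_noise_sd^2
  has_food <- cfg$context %in% c("foraging", "cover")
  has_cover <- cfg$context == "cover"
  patches <- if (has_food) default_patches(cfg) else NULL
  items <- if (has_food) rep(cfg$patch_items, nrow(patches)) else integer(0)
  patch_x <- patches$x; patch_y <- patches$y; patch_r <- patches$radius
  handling <- integer(m)                       # frames left handling food
  hiding <- logical(m)
  h_frames <- as.integer(round(cfg$handling_time_s * cfg$fps))
  p_enter <- 1 - (1 - cfg$p_enter_cover)^(1 / cfg$fps)
  p_exit <- 1 - (1 - cfg$p_exit_cover)^(1 / cfg$fps)
  depletion_frame <- NA_integer_

  # release from the central start cylinder, random initial headings
  ang0 <- stats::runif(m, 0, 2 * pi)
  rad0 <- cfg$start_radius * sqrt(stats::runif(m))
  pos <- cbind(rad0 * cos(ang0), rad0 * sin(ang0))
  theta <- stats::runif(m, 0, 2 * pi)
  noise <- matrix(rvonmises(nf * m, kappa), nf, m)

  out <- array(NA_real_, dim = c(nf, m, 2))
  out[1, , ] <- pos
  for (t in 2:nf) {
    hx <- cos(theta); hy <- sin(theta)
    if (m > 1L) {
      dx <- outer(pos[, 1], pos[, 1], `-`)     # dx[i,j] = x_i - x_j
      dy <- outer(pos[, 2], pos[, 2], `-`)
      D <- sqrt(dx^2 + dy^2); diag(D) <- Inf
      rep_mask <- D < cfg$r_repulsion
      # concentric shells: orientation up to r_alignment, attraction for
      # neighbours beyond it (the classic zonal schooling model)
      ali_mask <- D < cfg$r_alignment & !rep_mask
      att_mask <- D >= cfg$r_alignment & D < cfg$r_attraction
      # repulsion: away from the mean position of too-close neighbours
      rep_x <- rowSums(rep_mask * dx); rep_y <- rowSums(rep_mask * dy)
      any_rep <- rowSums(rep_mask) > 0L
      # alignment: mean heading of neighbours in the orientation shell
      ali_x <- as.numeric(ali_mask %*% hx); ali_y <- as.numeric(ali_mask %*% hy)
      none_ali <- rowSums(ali_mask) == 0L
      # attraction: towards mean position of far neighbours
      cnt <- rowSums(att_mask)
      att_x <- as.numeric(att_mask %*% pos[, 1]) / pmax(1, cnt) - pos[, 1]
      att_y <- as.numeric(att_mask %*% pos[, 2]) / pmax(1, cnt) - pos[, 2]
      none_att <- cnt == 0L
      dir_x <- ifelse(none_ali, 0, unit_x(ali_x, ali_y)) +
        ifelse(none_att, 0, unit_x(att_x, att_y))
      dir_y <- ifelse(none_ali, 0, unit_y(ali_x, ali_y)) +
        ifelse(none_att, 0, unit_y(att_x, att_y))
      lone <- none_ali & none_att
      dir_x[lone] <- hx[lone]; dir_y[lone] <- hy[lone]
      dir_x[any_rep] <- rep_x[any_rep]    # dx rows already point away
      dir_y[any_rep] <- rep_y[any_rep]
    } else {
      dir_x <- hx; dir_y <- hy
    }
    speed_fac <- rep(1, m)
    if (has_food && any(items > 0L)) {
      speed_fac[] <- cfg$feed_slowdown
      active <- which(items > 0L)
      pdx <- outer(pos[, 1], patch_x[active], `-`)
      pdy <- outer(pos[, 2], patch_y[active], `-`)
      pd <- sqrt(pdx^2 + pdy^2)
      near <- max.col(-pd, ties.method = "first")
      near_d <- pd[cbind(seq_len(m), near)]
      drawn <- near_d < cfg$detection_radius & handling == 0L & !hiding
      if (any(drawn)) {
        tx <- patch_x[active][near[drawn]] - pos[drawn, 1]
        ty <- patch_y[active][near[drawn]] - pos[drawn, 2]
        # patch attraction dominates social forces
        sx <- unit_x(dir_x[drawn], dir_y[drawn])
        sy <- unit_y(dir_x[drawn], dir_y[drawn])
        dir_x[drawn] <- sx + 3 * unit_x(tx, ty)
        dir_y[drawn] <- sy + 3 * unit_y(tx, ty)
      }
      # eating: one item per agent per contact frame
      for (i in which(near_d < patch_r[active][near] &
                      handling == 0L & !hiding)) {
        pa <- active[near[i]]
        if (items[pa] > 0L) {
          items[pa] <- items[pa] - 1L
          handling[i] <- h_frames
          if (sum(items) == 0L) depletion_frame <- t - 1L
        }
      }
    } else if (has_food) {
      speed_fac[] <- cfg$post_depletion_speedup
    }
    if (has_cover) {
      in_cov <- sqrt(rowSums(pos^2)) < cfg$cover_radius
      starts <- !hiding & in_cov & stats::runif(m) < p_enter
      stops <- hiding & stats::runif(m) < p_exit
      hiding <- (hiding | starts) & !stops
      speed_fac[hiding] <- 0
    }
    feeding <- handling > 0L
    speed_fac[feeding] <- 0
    handling[feeding] <- handling[feeding] - 1L
    # wall avoidance: blend in an inward push near the boundary
    w <- sqrt(rowSums(pos^2))
    close_wall <- w > 0.8 * R
    if (any(close_wall)) {
      push <- 2 * (w[close_wall] - 0.8 * R) / (0.2 * R)
      sx <- unit_x(dir_x[close_wall], dir_y[close_wall])
      sy <- unit_y(dir_x[close_wall], dir_y[close_wall])
      dir_x[close_wall] <- sx - push * pos[close_wall, 1] / w[close_wall]
      dir_y[close_wall] <- sy - push * pos[close_wall, 2] / w[close_wall]
    }
    # turn-rate-limited reorientation towards the desired direction
    dtheta <- atan2(dir_y, dir_x) - theta
    dtheta <- atan2(sin(dtheta), cos(dtheta))       # wrap to (-pi, pi]
    dtheta <- pmin(cfg$max_turn, pmax(-cfg$max_turn, dtheta))
    theta <- theta + dtheta + noise[t, ]
    pos <- pos + step_len * speed_fac * cbind(cos(theta), sin(theta))
    # hard wall: project back onto the arena
    w <- sqrt(rowSums(pos^2))
    outw <- w > R - 1
    if (any(outw)) pos[outw, ] <- pos[outw, ] * (R - 1) / w[outw]
    if (any(sqrt(rowSums(pos^2)) > R)) {
      stop("internal error: agent left the arena")   # wall model contract
    }
    out[t, , ] <- pos
  }
  meta <- trial_metadata(
    trial_id = trial_id, group_id = group_id, context = cfg$context,
    trial_number = trial_number,
    arena = list(centre = c(0, 0), radius = R),
    food_patches = patches,
    cover = if (has_cover) list(centre = c(0, 0),
                                radius = cfg$cover_radius) else NULL,
    depletion_frame = if (cfg$context == "foraging") {
      if (is.na(depletion_frame)) nf else depletion_frame
    } else if (has_cover && !is.na(depletion_frame)) depletion_frame
      else NULL,
    body_length_mm = cfg$body_length_mm, fps = cfg$fps)
  list(trajectory = trajectory(out, fps = cfg$fps, trial_id = trial_id,
                               ids = paste0(group_id, "_f", seq_len(m))),
       metadata = meta)
}

unit_x <- function(x, y) { n <- sqrt(x^2 + y^2); x / (n + (n == 0)) }
unit_y <- function(x, y) { n <- sqrt(x^2 + y^2); y / (n + (n == 0)) }

# deterministic per-trial substream below 2^31
trial_seed <- function(seed, group, context_idx, trial) {
  (seed * 1000003L + group * 7919L + context_idx * 611L + trial * 13L) %%
    2147483647L
}

#' Simulate the full group-assay experiment
#'
#' Draws group- and individual-level preferred-speed traits and runs the
#' study design: for each group one open trial, `foraging_trials` foraging
#' trials and `cover_trials` cover trials (defaults 1, 4, 2; 25 groups of
#' 5 gives the 175-trial design). Each trial gets its own deterministic
#' seed substream derived from `(seed, group, context, trial)`.
#'
#' @param cfg base [sim_config()]; its `context` and `duration_s` are
#'   overridden per trial.
#' @param n_groups number of groups; default 25.
#' @param foraging_trials,cover_trials trials per group in each context.
#' @param durations named list/vector of per-context trial durations in
#'   seconds, e.g. `c(open = 60, foraging = 120, cover = 120)`; `NULL`
#'   uses the protocol durations.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, trajectory, metadata and ground-truth
#'   trait CSVs are written there.
#' @return (invisibly when writing) list with `trials` (list of
#'   `list(trajectory, metadata)`), `truth` (data frame of trait draws) and
#'   `files` (paths written, or `NULL`).
#' @export
simulate_experiment <- function(cfg = sim_config(), n_groups = 25,
                                foraging_trials = 4, cover_trials = 2,
                                durations = NULL, seed = 1,
                                out_dir = NULL) {
  set.seed(seed)
  m <- cfg$n_fish
  g_off <- stats::rnorm(n_groups, 0, cfg$v_pref_group_sd)
  i_off <- matrix(stats::rnorm(n_groups * m, 0, cfg$v_pref_ind_sd),
                  n_groups, m)
  contexts <- c("open", "foraging", "cover")
  n_trials <- c(open = 1L, foraging = as.integer(foraging_trials),
                cover = as.integer(cover_trials))
  trials <- list()
  truth <- data.frame(group_id = sprintf("g%02d", seq_len(n_groups)),
                      group_trait = g_off)
  for (f in seq_len(m)) truth[[paste0("ind_trait_f", f)]] <- i_off[, f]
  for (g in seq_len(n_groups)) {
    gid <- sprintf("g%02d", g)
    for (ci in seq_along(contexts)) {
      ctx <- contexts[ci]
      for (tr in seq_len(n_trials[[ctx]])) {
        tcfg <- cfg
        tcfg$context <- ctx
        tcfg$duration_s <- if (!is.null(durations)) durations[[ctx]] else
          c(open = 1800, foraging = 300, cover = 600)[[ctx]]
        tid <- sprintf("%s_%s_t%d", gid, ctx, tr)
        trials[[tid]] <- simulate_trial(
          tcfg, group_trait = g_off[g], individual_traits = i_off[g, ],
          seed = trial_seed(seed, g, ci, tr),
          trial_id = tid, group_id = gid, trial_number = tr)
      }
    }
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tf <- file.path(out_dir, "trajectories.csv")
    mf <- file.path(out_dir, "metadata.csv")
    gf <- file.path(out_dir, "ground_truth.csv")
    write_trajectories(lapply(trials, `[[`, "trajectory"), tf)
    write_trial_metadata(lapply(trials, `[[`, "metadata"), mf)
    utils::write.csv(truth, gf, row.names = FALSE)
    files <- c(trajectories = tf, metadata = mf, truth = gf)
  }
  res <- list(trials = trials, truth = truth, files = files)
  if (is.null(out_dir)) res else invisible(res)
}
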