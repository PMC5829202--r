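# Fixture builders used across the test files. Everything is generated in
# code; no data files are read.

# constant-velocity track: fish i starts at starts[i, ] and moves at
# `vel` mm/frame
line_traj <- function(n_frames = 60, starts = rbind(c(0, 0), c(10, 0)),
                      vel = c(1, 0), fps = 24, trial_id = "line") {
  m <- nrow(starts)
  pos <- array(NA_real_, dim = c(n_frames, m, 2))
  t <- seq_len(n_frames) - 1
  for (i in seq_len(m)) {
    pos[, i, 1] <- starts[i, 1] + t * vel[1]
    pos[, i, 2] <- starts[i, 2] + t * vel[2]
  }
  trajectory(pos, fps = fps, trial_id = trial_id, smoothed = TRUE)
}

# fish on concentric circles, constant angular step (rad/frame)
circle_traj <- function(n_frames = 200, radii = c(100, 150),
                        ang_step = 0.05, fps = 24) {
  m <- length(radii)
  pos <- array(NA_real_, dim = c(n_frames, m, 2))
  t <- seq_len(n_frames) - 1
  for (i in seq_len(m)) {
    pos[, i, 1] <- radii[i] * cos(t * ang_step)
    pos[, i, 2] <- radii[i] * sin(t * ang_step)
  }
  trajectory(pos, fps = fps, trial_id = "circle", smoothed = TRUE)
}

# smooth correlated random walk, gap-free
rand_traj <- function(n_frames = 100, m = 5, seed = 1, fps = 24) {
  set.seed(seed)
  pos <- array(NA_real_, dim = c(n_frames, m, 2))
  for (i in seq_len(m)) {
    th <- cumsum(stats::rnorm(n_frames, 0, 0.15)) + stats::runif(1, 0, 6)
    step <- 1.5
    pos[, i, 1] <- cumsum(step * cos(th)) + stats::runif(1, -50, 50)
    pos[, i, 2] <- cumsum(step * sin(th)) + stats::runif(1, -50, 50)
  }
  trajectory(pos, fps = fps, trial_id = paste0("rand", seed),
             smoothed = TRUE)
}

open_meta <- function(trial_id = "line", group_id = "g01") {
  trial_metadata(trial_id, group_id, "open")
}

rotate_traj <- function(traj, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pos <- traj$positions
  for (i in seq_len(dim(pos)[2])) {
    xy <- pos[, i, ] %*% t(R)
    pos[, i, 1] <- xy[, 1] + shift[1]
    pos[, i, 2] <- xy[, 2] + shift[2]
  }
  trajectory(pos, fps = traj$fps, trial_id = traj$trial_id,
             ids = traj$ids, smoothed = traj$smoothed)
}

# small simulated experiment shared by pipeline tests
small_experiment <- function(seed = 5, n_groups = 3) {
  simulate_experiment(
    sim_config(), n_groups = n_groups,
    durations = c(open = 30, foraging = 90, cover = 30), seed = seed)
}

tiny_pipeline_config <- function(out_dir = NULL, seed = 5) {
  pipeline_config(
    out_dir = out_dir, n_groups = 3,
    durations = c(open = 30, foraging = 90, cover = 30),
    mcmc = list(nitt = 600, burnin = 100, thin = 2, chains = 2),
    seed = seed)
}
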