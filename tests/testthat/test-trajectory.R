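test_that("trajectory CSV round trip is lossless and joins metadata", {
  tr1 <- rand_traj(40, m = 3, seed = 1)
  tr2 <- rand_traj(40, m = 3, seed = 2)
  tr2$trial_id <- "rand2b"
  trajs <- list(rand1 = tr1, rand2b = tr2)
  tf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".csv")
  write_trajectories(trajs, tf, digits = 9)
  write_trial_metadata(list(open_meta("rand1"), open_meta("rand2b", "g02")),
                       mf)
  got <- read_trajectories(tf, mf)
  expect_named(got$trajectories, c("rand1", "rand2b"))
  expect_equal(got$trajectories$rand1$positions, tr1$positions,
               tolerance = 1e-8)
  expect_equal(got$trajectories$rand2b$positions, tr2$positions,
               tolerance = 1e-8)
  expect_equal(got$trajectories$rand1$fps, 24)
  expect_equal(got$metadata$rand2b$group_id, "g02")
})

test_that("pixel-unit files are scaled to mm by the declared factor", {
  tf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".csv")
  writeLines(c("# units: px", "# scale: 0.5", "# fps: 24",
               "trial_id,frame,fish_id,x,y",
               "t1,0,f1,100,40", "t1,1,f1,102,40"), tf)
  write_trial_metadata(open_meta("t1"), mf)
  got <- read_trajectories(tf, mf)
  expect_equal(got$trajectories$t1$positions[1, 1, ], c(50, 20))
  expect_equal(got$trajectories$t1$positions[2, 1, 1], 51)
})

test_that("malformed trajectory files are rejected with informative errors", {
  mf <- tempfile(fileext = ".csv")
  write_trial_metadata(open_meta("t1"), mf)
  hdr <- c("# units: mm", "# scale: 1", "# fps: 24",
           "trial_id,frame,fish_id,x,y")
  gap <- tempfile(fileext = ".csv")
  writeLines(c(hdr, "t1,0,f1,0,0", "t1,1,f1,1,0", "t1,3,f1,3,0"), gap)
  expect_error(read_trajectories(gap, mf), "gap at frame 2")
  dup <- tempfile(fileext = ".csv")
  writeLines(c(hdr, "t1,0,f1,0,0", "t1,1,f1,1,0", "t1,1,f1,1,0"), dup)
  expect_error(read_trajectories(dup, mf), "non-monotone|duplicated")
  nometa <- tempfile(fileext = ".csv")
  writeLines(c(hdr, "t2,0,f1,0,0", "t2,1,f1,1,0"), nometa)
  expect_error(read_trajectories(nometa, mf), "no metadata")
})

test_that("fill_gaps interpolates linearly and is idempotent", {
  pos <- array(NA_real_, dim = c(5, 1, 2))
  pos[, 1, 1] <- c(0, NA, 2, NA, NA)   # interior gap + trailing gap
  pos[, 1, 2] <- c(0, NA, 0, NA, NA)
  tr <- trajectory(pos, trial_id = "gappy")
  filled <- fill_gaps(tr, max_gap = 3)
  expect_equal(filled$positions[2, 1, ], c(1, 0))  # linear midpoint
  expect_equal(filled$positions[4, 1, ], c(2, 0))  # trailing -> nearest
  expect_equal(filled$positions[5, 1, ], c(2, 0))
  expect_false(anyNA(filled$positions))
  expect_identical(fill_gaps(filled, max_gap = 3)$positions,
                   filled$positions)
  full <- rand_traj(30, 2, seed = 3)
  expect_equal(fill_gaps(full)$positions, full$positions)
})

test_that("fill_gaps refuses gaps longer than max_gap, naming the span", {
  pos <- array(0, dim = c(80, 1, 2))
  pos[, 1, 1] <- seq_len(80)
  pos[11:60, 1, 1] <- NA; pos[11:60, 1, 2] <- NA
  tr <- trajectory(pos, trial_id = "longgap", ids = "fishA")
  expect_error(fill_gaps(tr, max_gap = 15), "fishA.*50 frames.*10-59")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  # linear motion: any window must leave it untouched
  tr <- line_traj(60, rbind(c(0, 5)), vel = c(1.3, -0.4))
  sm <- smooth_trajectory(tr, window = 15, polyorder = 3)
  expect_equal(sm$positions, tr$positions, tolerance = 1e-9)
  expect_true(sm$smoothed)
  # quadratic path, checked against an independent per-window least-squares
  # polynomial fit (the defining property of the filter)
  n <- 60; t <- seq_len(n) - 1
  pos <- array(NA_real_, dim = c(n, 1, 2))
  pos[, 1, 1] <- 0.02 * t^2 - t
  pos[, 1, 2] <- -0.01 * t^2 + 0.5 * t + 3
  trq <- trajectory(pos, trial_id = "quad", smoothed = TRUE)
  smq <- smooth_trajectory(trq, window = 15, polyorder = 3)
  oracle <- function(x, w, p) {
    h <- (w - 1) / 2; n <- length(x)
    sapply(seq_len(n), function(i) {
      idx <- max(1, i - h):min(n, i + h)
      deg <- min(p, length(idx) - 1)
      X <- outer(idx, 0:deg, `^`)          # raw Vandermonde, uncentred
      beta <- qr.solve(X, x[idx])
      sum(beta * i^(0:deg))
    })
  }
  expect_equal(smq$positions[, 1, 1], oracle(pos[, 1, 1], 15, 3),
               tolerance = 1e-6)
  expect_equal(smq$positions[, 1, 2], oracle(pos[, 1, 2], 15, 3),
               tolerance = 1e-6)
})

test_that("smoothing contracts noise and validates its arguments", {
  set.seed(42)
  n <- 120
  pos <- array(NA_real_, dim = c(n, 1, 2))
  pos[, 1, 1] <- rep(c(1, -1), length.out = n)   # alternating +/-1 mm
  pos[, 1, 2] <- 0
  tr <- trajectory(pos, trial_id = "noisy")
  sm <- smooth_trajectory(tr, window = 15, polyorder = 3)
  expect_lt(stats::var(sm$positions[, 1, 1]),
            stats::var(pos[, 1, 1]))
  expect_error(smooth_trajectory(tr, window = 14), "odd")
  expect_error(smooth_trajectory(tr, window = 15, polyorder = 15),
               "polyorder")
  expect_error(smooth_trajectory(tr, window = 121 * 2 + 1), "exceeds")
  gappy <- trajectory(array(c(0, NA, 2, 0, NA, 0), dim = c(3, 1, 2)))
  expect_error(smooth_trajectory(gappy, window = 3, polyorder = 1),
               "missing")
})

test_that("smoothing is translation- and rotation-equivariant", {
  tr <- rand_traj(80, m = 3, seed = 7)
  sm <- smooth_trajectory(tr)
  for (ang in c(0.7, 2.1)) {
    moved <- rotate_traj(tr, ang, shift = c(123, -45))
    sm_moved <- smooth_trajectory(moved)
    expect_equal(sm_moved$positions, rotate_traj(sm, ang,
                                                 c(123, -45))$positions,
                 tolerance = 1e-9)
  }
  expect_identical(sm$ids, tr$ids)
  expect_equal(dim(sm$positions), dim(tr$positions))
})
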