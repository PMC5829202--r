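test_that("centroid is the member mean and residuals sum to zero", {
  pos <- array(NA_real_, dim = c(3, 5, 2))
  pos[, , 1] <- 10; pos[, , 2] <- -3
  expect_equal(compute_centroid(trajectory(pos)),
               cbind(rep(10, 3), rep(-3, 3)))
  tr <- line_traj(10, rbind(c(0, 0), c(2, 0)), vel = c(0.5, 0.5))
  expect_equal(compute_centroid(tr)[1, ], c(1, 0))
  cloud <- rand_traj(30, m = 5, seed = 4)
  cen <- compute_centroid(cloud)
  res_x <- rowSums(cloud$positions[, , 1] - cen[, 1])
  res_y <- rowSums(cloud$positions[, , 2] - cen[, 2])
  expect_lt(max(abs(c(res_x, res_y))), 1e-9)
})

test_that("speeds convert mm/frame to cm/s and match the chord formula", {
  still <- line_traj(20, rbind(c(3, 3)), vel = c(0, 0))
  expect_equal(compute_speeds(still), matrix(0, 20, 1))
  tr <- line_traj(20, rbind(c(0, 0)), vel = c(1, 0), fps = 24)
  expect_equal(compute_speeds(tr), matrix(2.4, 20, 1))  # 1 mm x 24 Hz
  r <- 120; th <- 0.04
  circ <- circle_traj(100, radii = r, ang_step = th, fps = 24)
  expected <- 2 * r * sin(th / 2) * 24 / 10   # chord length per frame
  expect_equal(unname(compute_speeds(circ)[10, 1]), expected,
               tolerance = 1e-9)
})

test_that("headings follow displacement with carry-forward below min_step", {
  tr <- line_traj(10, rbind(c(0, 0)), vel = c(2, 0))
  hd <- compute_headings(tr)
  expect_equal(hd[, 1, 1], rep(1, 10))
  expect_equal(hd[, 1, 2], rep(0, 10))
  # moves +x for 5 frames then jitters below min_step: heading persists
  pos <- array(0, dim = c(10, 1, 2))
  pos[1:5, 1, 1] <- 0:4
  pos[6:10, 1, 1] <- 4 + c(0.05, 0, 0.05, 0, 0.05)
  jit <- trajectory(pos, smoothed = TRUE)
  hd <- compute_headings(jit, min_step = 0.2)
  expect_equal(hd[, 1, 1], rep(1, 10))
  # circular motion: heading is the chord direction, within one step angle
  circ <- circle_traj(100, radii = 100, ang_step = 0.05)
  hd <- compute_headings(circ)
  t <- 50
  tangent <- c(-sin((t - 1) * 0.05), cos((t - 1) * 0.05))
  ang_err <- acos(sum(hd[t, 1, ] * tangent))
  expect_lt(abs(ang_err), 0.05)
  # undefined before any valid step
  pos2 <- array(0, dim = c(5, 1, 2))
  expect_true(all(is.na(compute_headings(trajectory(pos2))[, 1, ])))
})

test_that("polarization matches hand-computed order parameters", {
  mk <- function(...) {
    angs <- c(...)
    h <- array(NA_real_, dim = c(1, length(angs), 2))
    h[1, , 1] <- cos(angs); h[1, , 2] <- sin(angs)
    h
  }
  expect_equal(compute_polarization(mk(0.3, 0.3, 0.3, 0.3, 0.3)), 1)
  expect_equal(compute_polarization(mk(0, pi)), 0)
  expect_equal(compute_polarization(mk(0, pi / 2, pi)), 1 / 3)
  # permutation invariance and [0, 1] bounds on random headings
  set.seed(9)
  angs <- stats::runif(5, 0, 2 * pi)
  p1 <- compute_polarization(mk(angs))
  p2 <- compute_polarization(mk(sample(angs)))
  expect_equal(p1, p2)
  expect_gte(p1, 0); expect_lte(p1, 1)
  # a single defined heading leaves polarization undefined
  h <- mk(0, 1)
  h[1, 2, ] <- NA
  expect_true(is.na(compute_polarization(h)))
})

test_that("cohesion distances match brute-force Euclidean computation", {
  pos <- array(NA_real_, dim = c(2, 3, 2))
  pos[, , 1] <- 7; pos[, , 2] <- 7
  expect_equal(compute_cohesion(trajectory(pos)), matrix(0, 2, 3))
  two <- line_traj(5, rbind(c(0, 0), c(100, 0)), vel = c(0, 1))
  expect_equal(compute_cohesion(two), matrix(5, 5, 2))  # 10 cm apart
  cloud <- rand_traj(20, m = 5, seed = 6)
  cen <- compute_centroid(cloud)
  brute <- sapply(1:5, function(i) {
    sqrt((cloud$positions[, i, 1] - cen[, 1])^2 +
         (cloud$positions[, i, 2] - cen[, 2])^2) / 10
  })
  expect_equal(compute_cohesion(cloud), brute, tolerance = 1e-12)
})

test_that("in_front uses strict projection and needs a moving centroid", {
  # group translating +x; fish 1 ahead of, fish 3 at, fish 2 behind centroid
  starts <- rbind(c(10, 0), c(-10, 0), c(0, 0))
  tr <- line_traj(20, starts, vel = c(2, 0))
  infr <- compute_in_front(tr)
  expect_true(all(infr[, 1]))
  expect_false(any(infr[, 2]))
  expect_false(any(infr[, 3]))   # exactly at centroid: strict > 0
  still <- line_traj(20, starts, vel = c(0, 0))
  expect_true(all(is.na(compute_in_front(still))))
})

test_that("trial summaries capture leadership structure", {
  expect_equal(leadership_variance(c(1, 0.5, 0.5, 0.5, 0)), 0.1)
  expect_equal(leadership_variance(rep(0.4, 5)), 0)
  starts <- rbind(c(15, 0), c(-5, 3), c(-5, -3), c(-3, 1), c(-2, -1))
  tr <- line_traj(100, starts, vel = c(2, 0.3))
  meta <- open_meta("line", "g07")
  tm <- summarize_trial(tr, meta)
  expect_s3_class(tm, "trial_metrics")
  expect_equal(tm$individual$front_proportion[1], 1)
  expect_true(all(tm$individual$front_proportion[-1] < 1))
  expect_gt(tm$group$leadership_variance, 0)
  expect_equal(tm$group$median_polarization, 1)
  expect_equal(tm$individual$group_id, rep("g07", 5))
  expect_error(summarize_trial(tr, meta, c(50, 50)), "empty")
  still <- line_traj(30, starts, vel = c(0, 0))
  expect_error(summarize_trial(still, meta), "no frames")
})

test_that("foraging trials split at the depletion frame", {
  pos <- array(stats::rnorm(7200 * 2 * 2), dim = c(7200, 2, 2))
  tr <- trajectory(pos, smoothed = TRUE)
  meta <- trial_metadata("t", "g", "foraging", depletion_frame = 1200,
                        food_patches = data.frame(x = 0, y = 0, radius = 25,
                                                  n_items = 5))
  w <- split_foraging_trial(tr, meta)
  expect_equal(w$pre, c(0L, 1200L))
  expect_equal(w$post, c(1200L, 7200L))
  expect_equal(diff(w$pre), 1200L)
  expect_equal(diff(w$post), 6000L)
  meta0 <- trial_metadata("t", "g", "foraging", depletion_frame = 0,
                          food_patches = meta$food_patches)
  w0 <- split_foraging_trial(tr, meta0)
  expect_error(summarize_trial(tr, meta0, w0$pre), "empty")
  meta_bad <- trial_metadata("t", "g", "foraging", depletion_frame = 9999,
                             food_patches = meta$food_patches)
  expect_error(split_foraging_trial(tr, meta_bad), "outside")
})

test_that("metrics are invariant under rotation, translation, relabelling", {
  for (seed in 1:3) {
    tr <- rand_traj(60, m = 5, seed = seed)
    moved <- rotate_traj(tr, 1.1, shift = c(-200, 77))
    expect_equal(compute_speeds(moved), compute_speeds(tr),
                 tolerance = 1e-9)
    expect_equal(compute_cohesion(moved), compute_cohesion(tr),
                 tolerance = 1e-9)
    expect_equal(compute_polarization(compute_headings(moved)),
                 compute_polarization(compute_headings(tr)),
                 tolerance = 1e-9)
    expect_identical(compute_in_front(moved), compute_in_front(tr))
  }
})

test_that("halving the frame rate leaves speeds unchanged on smooth paths", {
  circ <- circle_traj(200, radii = 150, ang_step = 0.02, fps = 24)
  half <- trajectory(circ$positions[seq(1, 200, by = 2), , , drop = FALSE],
                     fps = 12, smoothed = TRUE)
  s_full <- compute_speeds(circ)[1, 1]
  s_half <- compute_speeds(half)[1, 1]
  expect_equal(s_half, s_full, tolerance = 1e-3)
})
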