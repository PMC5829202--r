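test_that("the LMM generator is seeded and honours its limits", {
  g1 <- generate_lmm_data(seed = 3)
  g2 <- generate_lmm_data(seed = 3)
  expect_identical(g1$data, g2$data)
  expect_equal(g1$truth$r_group, 1 / 2.5)
  # no group/individual signal: group means scatter like iid noise
  g0 <- generate_lmm_data(n_groups = 200, n_per_group = 5, n_obs = 4,
                          v_group = 0, v_id = 0, v_res = 1, seed = 5)
  gm <- tapply(g0$data$y, g0$data$group_id, mean)
  expect_lt(stats::var(gm), 3 * 1 / 20)     # V_res / (n_per_group * n_obs)
  # dominant group variance: empirical ICC near 1
  gbig <- generate_lmm_data(n_groups = 40, v_group = 100, v_id = 0.01,
                            v_res = 0.01, seed = 6)
  av <- stats::anova(stats::aov(y ~ group_id, gbig$data))
  icc <- 1 - av["Residuals", "Mean Sq"] / av["group_id", "Mean Sq"]
  expect_gt(icc, 0.98)
})

test_that("point repeatability ratios behave at the boundaries", {
  expect_equal(repeatability(c(group = 0, id = 2, res = 1))$point[1], 0)
  r <- repeatability(c(group = 5, id = 0, res = 1e-8))
  expect_gt(r$point[r$level == "group"], 0.999)
  expect_equal(repeatability(c(group = 1, res = 1))$point, 0.5)
  expect_error(repeatability(c(1, 2, 3)), "named")
  expect_error(repeatability(c(group = -1, res = 1)), "non-negative")
})

test_that("moment estimator recovers balanced-design components", {
  g <- generate_lmm_data(n_groups = 60, n_per_group = 5, n_obs = 4,
                         context_effects = c(0, 1, 2, 3),
                         v_group = 1, v_id = 0.5, v_res = 1, seed = 21)
  mo <- moment_estimator(y ~ context, g$data,
                         random = c("group_id", "individual_id"))
  expect_equal(mo$v_group, 1, tolerance = 0.35)
  expect_equal(mo$v_id, 0.5, tolerance = 0.35)
  expect_equal(mo$v_res, 1, tolerance = 0.1)
  expect_false(mo$confounded)
  # zero within-individual spread: residual variance collapses to 0
  d <- expand.grid(obs = 1:3, individual_id = paste0("i", 1:4),
                   group_id = c("a", "b"))
  d$y <- rep(c(1, 2, 3, 4, 10, 11, 12, 13), each = 3)
  mo0 <- moment_estimator(y ~ 1, d, random = c("group_id", "individual_id"))
  expect_equal(mo0$v_res, 0)
  expect_gt(mo0$v_id, 0)
  # one observation per individual: id and residual confounded
  d1 <- d[d$obs == 1, ]
  expect_warning(
    mo1 <- moment_estimator(y ~ 1, d1,
                            random = c("group_id", "individual_id")),
    NA)
  expect_true(mo1$confounded)
  expect_true(is.na(mo1$v_id))
})

test_that("the Gibbs sampler agrees with lme4 on one balanced dataset", {
  skip_if_not_installed("lme4")
  g <- generate_lmm_data(n_groups = 40, n_per_group = 5, n_obs = 4,
                         context_effects = c(0, 0.5, 1, -0.5),
                         v_group = 1, v_id = 0.5, v_res = 1, seed = 31)
  fit <- rc_lmm(y ~ context, g$data,
                random = c("group_id", "individual_id"),
                nitt = 4000, burnin = 800, thin = 4, chains = 2, seed = 9)
  vc <- as.data.frame(lme4::VarCorr(
    lme4::lmer(y ~ context + (1 | group_id) + (1 | individual_id),
               g$data)))
  ref <- stats::setNames(vc$vcov, vc$grp)
  post <- colMeans(fit$draws[, c("V_group", "V_id", "V_res")])
  expect_equal(unname(post["V_group"]), unname(ref["group_id"]),
               tolerance = 0.15)
  expect_equal(unname(post["V_id"]), unname(ref["individual_id"]),
               tolerance = 0.15)
  expect_equal(unname(post["V_res"]), unname(ref["Residual"]),
               tolerance = 0.1)
  # fixed effects recovered too
  expect_equal(unname(coef(fit)["contextc3"]), 1, tolerance = 0.25)
})

test_that("no group signal leaves the group variance near zero", {
  g <- generate_lmm_data(n_groups = 40, n_per_group = 5, n_obs = 4,
                         v_group = 0, v_id = 0.3, v_res = 1, seed = 41)
  fit <- rc_lmm(y ~ 1, g$data, random = c("group_id", "individual_id"),
                nitt = 3000, burnin = 600, thin = 4, chains = 2, seed = 2)
  post <- colMeans(fit$draws[, c("V_group", "V_res")])
  expect_lt(post["V_group"], 0.1 * post["V_res"])
  rep_fit <- repeatability(fit)
  expect_false(rep_fit$significant[rep_fit$level == "group"])
})

test_that("a fixed-effects-only model reduces to Gaussian mean estimation", {
  set.seed(8)
  y <- stats::rnorm(300, mean = 4.2, sd = 1.5)
  fit <- rc_lmm(y ~ 1, data.frame(y = y), random = NULL,
                nitt = 2000, burnin = 400, thin = 4, chains = 2, seed = 3)
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(y),
               tolerance = 0.05)
  expect_identical(fit$vnames, "V_res")
  expect_equal(nrow(repeatability(fit)), 0L)
})

test_that("repeatability is scale-invariant, components scale by c^2", {
  g <- generate_lmm_data(n_groups = 30, seed = 51)
  d2 <- g$data; d2$y <- d2$y * 10
  mo1 <- moment_estimator(y ~ context, g$data,
                          random = c("group_id", "individual_id"))
  mo2 <- moment_estimator(y ~ context, d2,
                          random = c("group_id", "individual_id"))
  expect_equal(mo2$v_group, 100 * mo1$v_group, tolerance = 1e-9)
  expect_equal(mo2$v_res, 100 * mo1$v_res, tolerance = 1e-9)
  r1 <- repeatability(c(group = mo1$v_group, id = mo1$v_id,
                        res = mo1$v_res))
  r2 <- repeatability(c(group = mo2$v_group, id = mo2$v_id,
                        res = mo2$v_res))
  expect_equal(r1$point, r2$point, tolerance = 1e-12)
})

test_that("independent chains mix and agree within Monte-Carlo error", {
  g <- generate_lmm_data(n_groups = 30, seed = 61)
  fit <- rc_lmm(y ~ context, g$data,
                random = c("group_id", "individual_id"),
                nitt = 3000, burnin = 600, thin = 4, chains = 3, seed = 17)
  expect_true(all(fit$psrf[fit$vnames] < 1.1))
  ch <- attr(fit$draws, "chain")
  m1 <- mean(fit$draws[ch == 1, "V_group"])
  m2 <- mean(fit$draws[ch == 2, "V_group"])
  expect_equal(m1, m2, tolerance = 0.15)
  # a different master seed moves draws but not the posterior mean (much)
  fit2 <- rc_lmm(y ~ context, g$data,
                 random = c("group_id", "individual_id"),
                 nitt = 3000, burnin = 600, thin = 4, chains = 2,
                 seed = 99)
  expect_equal(mean(fit$draws[, "V_group"]),
               mean(fit2$draws[, "V_group"]), tolerance = 0.1)
})

test_that("model validation rejects broken designs", {
  g <- generate_lmm_data(n_groups = 5, seed = 71)
  d <- g$data
  d$individual_id[d$individual_id == "g01_i1"] <- "g02_i1"  # crosses groups
  expect_error(rc_lmm(y ~ context, d,
                      random = c("group_id", "individual_id"),
                      nitt = 200, burnin = 50, chains = 1),
               "nested")
  d2 <- data.frame(y = stats::rnorm(5),
                   group_id = c("a", "a", "b", "b", "c"))
  expect_error(rc_lmm(y ~ 1, d2, random = "group_id",
                      nitt = 200, burnin = 50, chains = 1),
               "at least 2")
})

test_that("credible-interval comparison flags separated context levels", {
  g <- generate_lmm_data(n_groups = 25, n_per_group = 5, n_obs = 4,
                         context_effects = c(0, 5, 0.1, 0.05),
                         v_group = 0.5, v_id = 0.2, v_res = 0.5, seed = 81)
  fit <- rc_lmm(y ~ context, g$data,
                random = c("group_id", "individual_id"),
                nitt = 3000, burnin = 600, thin = 4, chains = 2, seed = 4)
  big <- compare_levels(fit, "c1", "c2")
  expect_true(big$non_overlap)
  small <- compare_levels(fit, "c1", "c3")
  expect_false(small$non_overlap)
  expect_lt(big$ci_a[["u95"]], big$ci_b[["l95"]])
  expect_error(compare_levels(fit, "c1", "nope"), "unknown level")
})
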