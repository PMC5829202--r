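#' Generate metric-level data from the random-intercept model
#'
#' Draws observations from the exact generative mirror of the model fitted
#' by [rc_lmm()]:
#' \deqn{y_{gic} = \mu + \beta_c + a_g + b_{gi} + e_{gic}}
#' with `a_g ~ N(0, v_group)`, `b_gi ~ N(0, v_id)`,
#' `e ~ N(0, v_res)`, a balanced design of `n_groups` groups x
#' `n_per_group` individuals x `n_obs` contexts. Returns the data together
#' with the simulated truth (components and realized random effects) so
#' that inference can be tested against ground truth.
#'
#' @param n_groups number of groups (>= 2); default 25, the study design.
#' @param n_per_group individuals per group; default 5.
#' @param n_obs observations per individual (context/trial levels);
#'   default 4.
#' @param mu grand mean; default 0.
#' @param context_effects numeric vector of length `n_obs` of fixed context
#'   effects (first is the reference, conventionally 0); default all 0.
#' @param v_group,v_id,v_res variance components (>= 0, `v_res` > 0).
#' @param seed integer seed.
#' @return list with `data` (data frame: `y, group_id, individual_id,
#'   context`) and `truth` (list of the generating parameters and realized
#'   effects).
#' @export
generate_lmm_data <- function(n_groups = 25, n_per_group = 5, n_obs = 4,
                              mu = 0, context_effects = rep(0, n_obs),
                              v_group = 1, v_id = 0.5, v_res = 1,
                              seed = 1) {
  stopifnot(n_groups >= 2, n_per_group >= 1, n_obs >= 1,
            v_group >= 0, v_id >= 0, v_res > 0,
            length(context_effects) == n_obs)
  set.seed(seed)
  a <- stats::rnorm(n_groups, 0, sqrt(v_group))
  b <- stats::rnorm(n_groups * n_per_group, 0, sqrt(v_id))
  gi <- expand.grid(context = seq_len(n_obs),
                    individual = seq_len(n_per_group),
                    group = seq_len(n_groups))
  idx_id <- (gi$group - 1L) * n_per_group + gi$individual
  e <- stats::rnorm(nrow(gi), 0, sqrt(v_res))
  y <- mu + context_effects[gi$context] + a[gi$group] + b[idx_id] + e
  data <- data.frame(
    y = y,
    group_id = sprintf("g%02d", gi$group),
    individual_id = sprintf("g%02d_i%d", gi$group, gi$individual),
    context = factor(paste0("c", gi$context)))
  list(data = data,
       truth = list(mu = mu, context_effects = context_effects,
                    v_group = v_group, v_id = v_id, v_res = v_res,
                    r_group = v_group / (v_group + v_id + v_res),
                    group_effects = a, individual_effects = b,
                    seed = seed))
}
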