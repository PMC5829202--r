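#' Gibbs-sampled Gaussian linear mixed model for repeatability analysis
#'
#' Fits the Gaussian random-intercept model
#' \deqn{y = X\beta + Z_g a + Z_i b + e,\quad
#'       a \sim N(0, V_{group} I),\; b \sim N(0, V_{id} I),\;
#'       e \sim N(0, V_{res} I)}
#' by Gibbs sampling, with a group-level random intercept and optionally an
#' individual-level random intercept nested within groups. This is the
#' variance-partitioning engine behind consistency repeatability: the
#' proportions of total variance attributable to group and to individual
#' identity (see [repeatability()]).
#'
#' Full conditionals are conjugate throughout: normal for the fixed effects
#' and each block of random intercepts, inverse-gamma for the variances.
#' Priors are diffuse-normal on `beta` (variance `beta_prior_var`) and
#' inverse-gamma(`ig_shape`, `ig_scale`) on each variance component —
#' non-informative proper priors. Several independent chains are run and
#' the potential scale reduction factor (PSRF) across chains is reported
#' for every variance component.
#'
#' @param formula model formula for the fixed part, e.g.
#'   `median_speed ~ context`.
#' @param data data frame containing the response, fixed-effect factors and
#'   the random-effect grouping columns.
#' @param random character vector naming the random-intercept columns: the
#'   first is the group factor, the optional second an individual factor
#'   nested within groups. Default `"group_id"`.
#' @param nitt total iterations per chain (default 20000).
#' @param burnin iterations discarded per chain (default 2000).
#' @param thin thinning interval (default 10).
#' @param chains number of independent chains (default 5).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param beta_prior_var prior variance of the fixed effects (default 1e8).
#' @param ig_shape,ig_scale inverse-gamma prior parameters for the variance
#'   components (default 0.001, 0.001).
#' @return an object of class `"rc_lmm"` with components `draws` (matrix of
#'   retained posterior draws, columns = fixed effects then variance
#'   components, with a `chain` attribute), `psrf`, `xlevels`, `call`.
#' @seealso [repeatability()], [moment_estimator()], [compare_levels()]
#' @examples
#' g <- generate_lmm_data(n_groups = 10, n_per_group = 3, n_obs = 2,
#'                        v_group = 1, v_id = 0.5, v_res = 1, seed = 1)
#' fit <- rc_lmm(y ~ context, g$data, random = c("group_id", "individual_id"),
#'               nitt = 1000, burnin = 200, thin = 5, chains = 2, seed = 1)
#' summary(fit)
#' @export
rc_lmm <- function(formula, data, random = "group_id",
                   nitt = 20000, burnin = 2000, thin = 10, chains = 5,
                   seed = 1, beta_prior_var = 1e8,
                   ig_shape = 0.001, ig_scale = 0.001) {
  if (is.null(random)) random <- character(0)
  stopifnot(length(random) <= 2, burnin < nitt, thin >= 1, chains >= 1)
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (anyNA(y)) stop("missing responses are not allowed")
  g <- NULL
  if (length(random) >= 1L) {
    g <- factor(data[[random[1]]])
    if (min(table(g)) < 2L) {
      stop("every group needs at least 2 observations")
    }
  }
  id <- NULL
  if (length(random) == 2L) {
    id <- factor(data[[random[2]]])
    # each individual must belong to exactly one group
    tab <- table(id, g) > 0
    if (any(rowSums(tab) > 1L)) {
      bad <- rownames(tab)[rowSums(tab) > 1L][1]
      stop(sprintf("individual '%s' appears in more than one group: %s",
                   bad, "individual ids must be nested within groups"))
    }
  }
  xlev <- stats::.getXlevels(attr(mf, "terms"), mf)
  vnames <- c(if (!is.null(g)) "V_group", if (!is.null(id)) "V_id", "V_res")
  all_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    all_draws[[ch]] <- gibbs_chain(
      y, X, if (is.null(g)) NULL else as.integer(g),
      if (is.null(id)) NULL else as.integer(id),
      nitt = nitt, burnin = burnin, thin = thin, seed = seed + ch - 1L,
      beta_prior_var = beta_prior_var,
      ig_shape = ig_shape, ig_scale = ig_scale)
  }
  psrf <- psrf_stat(all_draws)
  draws <- do.call(rbind, all_draws)
  attr(draws, "chain") <- rep(seq_len(chains),
                              each = nrow(all_draws[[1]]))
  structure(
    list(draws = draws, psrf = psrf, formula = formula, random = random,
         xlevels = xlev, n_obs = length(y), vnames = vnames,
         settings = list(nitt = nitt, burnin = burnin, thin = thin,
                         chains = chains, seed = seed),
         call = match.call()),
    class = "rc_lmm")
}

# One Gibbs chain. g_idx and i_idx are integer codes; i_idx may be NULL.
# Columns of the returned matrix: fixed effects, then V_group [, V_id], V_res.
gibbs_chain <- function(y, X, g_idx, i_idx, nitt, burnin, thin, seed,
                        beta_prior_var, ig_shape, ig_scale) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  has_g <- !is.null(g_idx)
  G <- if (has_g) max(g_idx) else 0L
  has_id <- !is.null(i_idx)
  M <- if (has_id) max(i_idx) else 0L
  XtX <- crossprod(X)
  n_g <- if (has_g) tabulate(g_idx, G) else NULL
  n_i <- if (has_id) tabulate(i_idx, M) else NULL
  # initial values from the data scale
  beta <- stats::coef(stats::lm.fit(X, y))
  beta[is.na(beta)] <- 0
  vy <- stats::var(y)
  v_g <- vy / 2; v_i <- if (has_id) vy / 4 else NULL; v_e <- vy / 2
  a <- numeric(G); b <- if (has_id) numeric(M) else NULL
  keep <- seq(burnin + thin, nitt, by = thin)
  out <- matrix(NA_real_, length(keep), p + 1L + has_g + has_id)
  colnames(out) <- c(colnames(X), if (has_g) "V_group",
                     if (has_id) "V_id", "V_res")
  k <- 0L
  for (it in seq_len(nitt)) {
    ranef <- (if (has_g) a[g_idx] else 0) + (if (has_id) b[i_idx] else 0)
    # beta | rest
    V <- chol2inv(chol(XtX / v_e + diag(1 / beta_prior_var, p)))
    m <- V %*% (crossprod(X, y - ranef) / v_e)
    beta <- as.numeric(m + t(chol(V)) %*% stats::rnorm(p))
    xb <- as.numeric(X %*% beta)
    # group intercepts | rest
    if (has_g) {
      r <- y - xb - (if (has_id) b[i_idx] else 0)
      s <- as.numeric(rowsum(r, g_idx, reorder = TRUE))
      vv <- 1 / (n_g / v_e + 1 / v_g)
      a <- stats::rnorm(G, vv * s / v_e, sqrt(vv))
      v_g <- 1 / stats::rgamma(1, ig_shape + G / 2,
                               ig_scale + sum(a^2) / 2)
    }
    # individual intercepts | rest
    if (has_id) {
      r <- y - xb - (if (has_g) a[g_idx] else 0)
      s <- as.numeric(rowsum(r, i_idx, reorder = TRUE))
      vv <- 1 / (n_i / v_e + 1 / v_i)
      b <- stats::rnorm(M, vv * s / v_e, sqrt(vv))
      v_i <- 1 / stats::rgamma(1, ig_shape + M / 2,
                               ig_scale + sum(b^2) / 2)
    }
    e <- y - xb - (if (has_g) a[g_idx] else 0) -
      (if (has_id) b[i_idx] else 0)
    v_e <- 1 / stats::rgamma(1, ig_shape + n / 2, ig_scale + sum(e^2) / 2)
    if (k < length(keep) && it == keep[k + 1L]) {
      k <- k + 1L
      out[k, ] <- c(beta, if (has_g) v_g, if (has_id) v_i, v_e)
    }
  }
  out
}

# Gelman-Rubin potential scale reduction factor per parameter.
psrf_stat <- function(chain_list) {
  m <- length(chain_list)
  if (m < 2L) return(stats::setNames(rep(NA_real_, ncol(chain_list[[1]])),
                                     colnames(chain_list[[1]])))
  n <- nrow(chain_list[[1]])
  sapply(colnames(chain_list[[1]]), function(p) {
    x <- sapply(chain_list, function(d) d[, p])
    mu <- colMeans(x)
    B <- n * stats::var(mu)
    W <- mean(apply(x, 2, stats::var))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' @export
print.rc_lmm <- function(x, ...) {
  cat("Gibbs-sampled Gaussian LMM (rc_lmm)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat("  random intercepts:", paste(x$random, collapse = " + "), "\n")
  s <- x$settings
  cat(sprintf("  %d chains x %d iterations (burnin %d, thin %d), %d draws\n",
              s$chains, s$nitt, s$burnin, s$thin, nrow(x$draws)))
  vt <- posterior_table(x)
  print(round(vt[x$vnames, ], 4))
  invisible(x)
}

posterior_table <- function(fit) {
  d <- fit$draws
  t(apply(d, 2, function(v) c(
    mean = mean(v),
    `l95` = unname(stats::quantile(v, 0.025)),
    `u95` = unname(stats::quantile(v, 0.975)))))
}

#' @export
summary.rc_lmm <- function(object, ...) {
  tab <- posterior_table(object)
  vn <- object$vnames
  res <- list(fixed = tab[setdiff(rownames(tab), vn), , drop = FALSE],
              variances = tab[vn, , drop = FALSE],
              psrf = object$psrf,
              repeatability = repeatability(object),
              settings = object$settings)
  class(res) <- "summary.rc_lmm"
  res
}

#' @export
print.summary.rc_lmm <- function(x, ...) {
  cat("Fixed effects (posterior mean, 95% CI):\n")
  print(round(x$fixed, 4))
  cat("\nVariance components:\n")
  print(round(x$variances, 4))
  cat("\nPSRF (potential scale reduction, across chains):\n")
  print(round(x$psrf, 3))
  cat("\nConsistency repeatability:\n")
  print(x$repeatability)
  invisible(x)
}

#' @export
coef.rc_lmm <- function(object, ...) {
  tab <- posterior_table(object)
  keep <- setdiff(rownames(tab), object$vnames)
  stats::setNames(tab[keep, "mean"], keep)
}

#' @export
plot.rc_lmm <- function(x, pars = x$vnames, ...) {
  ch <- attr(x$draws, "chain")
  old <- graphics::par(mfrow = c(length(pars), 1),
                       mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::matplot(
      matrix(x$draws[, p], ncol = max(ch)), type = "l", lty = 1,
      ylab = p, xlab = "", main = paste("trace:", p), ...)
  }
  invisible(x)
}
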