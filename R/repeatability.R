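#' Consistency repeatability from variance components
#'
#' Consistency repeatability is the intraclass correlation: the proportion
#' of total phenotypic variance (after fixed effects) attributable to a
#' grouping factor,
#' \deqn{R_{group} = V_{group} / (V_{group} + V_{id} + V_{res})}
#' and likewise for individual identity (the `V_id` term is omitted when no
#' individual component is modelled).
#'
#' For an [rc_lmm()] fit the ratio is computed per posterior draw and then
#' summarized (posterior mean and equal-tailed 95% CI), propagating the
#' posterior uncertainty; the ratio of posterior-mean components is also
#' reported as `point` for comparison with published point estimates. The
#' default method takes plain numeric components and returns the point
#' ratios directly.
#'
#' A component is flagged as significantly repeatable when the lower 2.5%
#' posterior quantile of its variance exceeds 1% of the posterior-mean
#' total variance — the operational form of "the 95% CI of the random
#' effect does not reach zero" for strictly positive variance draws.
#'
#' @param object an [rc_lmm()] fit, or a numeric vector of variance
#'   components named `group`, optionally `id`, and `res`.
#' @param ... unused.
#' @return an object of class `"repeatability"`: a data frame with one row
#'   per modelled identity level (`group`, `id`) and columns `point`,
#'   `mean`, `l95`, `u95`, `significant` (the latter four `NA` for the
#'   default method, which has no posterior).
#' @examples
#' repeatability(c(group = 0.85, id = 0.00, res = 0.87))   # R_group 0.49
#' repeatability(c(group = 1.70e-3, res = 4.18e-3))        # R_group 0.29
#' @export
repeatability <- function(object, ...) UseMethod("repeatability")

#' @rdname repeatability
#' @export
repeatability.default <- function(object, ...) {
  v <- object
  if (is.null(names(v)) || !all(c("group", "res") %in% names(v))) {
    stop("components must be named: group, [id,] res")
  }
  if (any(v < 0)) stop("variance components must be non-negative")
  has_id <- "id" %in% names(v)
  total <- v[["group"]] + (if (has_id) v[["id"]] else 0) + v[["res"]]
  rows <- data.frame(
    level = c("group", if (has_id) "id"),
    point = c(v[["group"]] / total, if (has_id) v[["id"]] / total),
    mean = NA_real_, l95 = NA_real_, u95 = NA_real_, significant = NA)
  structure(rows, class = c("repeatability", "data.frame"))
}

#' @rdname repeatability
#' @export
repeatability.rc_lmm <- function(object, ...) {
  d <- object$draws
  if (any(d[, object$vnames] < 0)) {
    stop("internal error: negative variance draw")    # sampler contract
  }
  if (!"V_group" %in% object$vnames) {
    # fixed-effects-only model: nothing to partition
    out <- data.frame(level = character(0), point = numeric(0),
                      mean = numeric(0), l95 = numeric(0),
                      u95 = numeric(0), significant = logical(0))
    return(structure(out, class = c("repeatability", "data.frame")))
  }
  has_id <- "V_id" %in% object$vnames
  tot <- d[, "V_group"] + (if (has_id) d[, "V_id"] else 0) + d[, "V_res"]
  pm <- colMeans(d[, object$vnames, drop = FALSE])
  tot_pm <- sum(pm)
  summ <- function(vname) {
    r <- d[, vname] / tot
    c(point = unname(pm[vname] / tot_pm),
      mean = mean(r),
      l95 = unname(stats::quantile(r, 0.025)),
      u95 = unname(stats::quantile(r, 0.975)),
      significant = unname(stats::quantile(d[, vname], 0.025)) >
        0.01 * tot_pm)
  }
  rows <- rbind(summ("V_group"), if (has_id) summ("V_id"))
  out <- data.frame(level = c("group", if (has_id) "id"), rows)
  out$significant <- as.logical(out$significant)
  structure(out, class = c("repeatability", "data.frame"))
}

#' @export
print.repeatability <- function(x, ...) {
  for (k in seq_len(nrow(x))) {
    if (is.na(x$mean[k])) {
      cat(sprintf("  R_%s = %.2f (point estimate)\n",
                  x$level[k], x$point[k]))
    } else {
      cat(sprintf("  R_%s = %.2f [%.2f-%.2f]%s (point %.2f)\n",
                  x$level[k], x$mean[k], x$l95[k], x$u95[k],
                  if (isTRUE(x$significant[k])) " *" else "", x$point[k]))
    }
  }
  invisible(x)
}

#' Method-of-moments variance components for a balanced nested design
#'
#' ANOVA estimator used as an independent oracle for the Gibbs sampler:
#' fixed effects are taken from the model formula, and the group /
#' individual-within-group / residual variance components are solved from
#' the expected mean squares of the nested ANOVA (negative solutions
#' truncated at zero). Exact for balanced designs; for mildly unbalanced
#' data average counts are used and a warning is issued.
#'
#' @inheritParams rc_lmm
#' @return list with `v_group`, `v_id` (NA when no individual factor),
#'   `v_res`, `confounded` (TRUE when individual and residual variance are
#'   inseparable, i.e. one observation per individual).
#' @export
moment_estimator <- function(formula, data, random = "group_id") {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  g <- factor(data[[random[1]]])
  has_id <- length(random) == 2L
  G <- nlevels(g)
  n <- length(y)
  # remove fixed effects first, then partition the residual
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  yadj <- y - X %*% stats::coef(stats::lm.fit(X, y)) + mean(y)
  data$.yadj <- as.numeric(yadj)
  data$.g <- g
  if (!has_id) {
    n_per <- table(g)
    if (max(n_per) != min(n_per)) {
      warning("unbalanced design; moment estimates are approximate")
    }
    k <- n / G
    av <- suppressWarnings(stats::anova(stats::aov(.yadj ~ .g, data)))
    ms_g <- av[".g", "Mean Sq"]
    ms_e <- av["Residuals", "Mean Sq"]
    return(list(v_group = max(0, (ms_g - ms_e) / k), v_id = NA_real_,
                v_res = ms_e, confounded = FALSE))
  }
  # label-combine so ids reused across groups stay nested
  id <- factor(paste(g, data[[random[2]]], sep = "/"))
  data$.id <- id
  M <- nlevels(id)
  obs_per_id <- table(id)
  ids_per_g <- rowSums(table(g, id) > 0)
  if (max(obs_per_id) != min(obs_per_id) ||
      max(ids_per_g) != min(ids_per_g)) {
    warning("unbalanced design; moment estimates are approximate")
  }
  k <- n / M            # obs per individual
  m <- M / G            # individuals per group
  if (k <= 1) {
    # one observation per individual: V_id and V_res not separable
    av <- suppressWarnings(stats::anova(stats::aov(.yadj ~ .g, data)))
    ms_g <- av[".g", "Mean Sq"]; ms_e <- av["Residuals", "Mean Sq"]
    return(list(v_group = max(0, (ms_g - ms_e) / m), v_id = NA_real_,
                v_res = ms_e, confounded = TRUE))
  }
  # individual ids are globally unique, so `.g + .id` yields the nested
  # sequential SS without materializing the huge .g:.id dummy matrix
  av <- suppressWarnings(stats::anova(stats::aov(.yadj ~ .g + .id, data)))
  ms_g <- av[".g", "Mean Sq"]
  ms_i <- av[".id", "Mean Sq"]
  ms_e <- av["Residuals", "Mean Sq"]
  v_res <- ms_e
  v_id <- max(0, (ms_i - ms_e) / k)
  v_group <- max(0, (ms_g - ms_i) / (k * m))
  list(v_group = v_group, v_id = v_id, v_res = v_res, confounded = FALSE)
}

#' Compare two fixed-effect levels by credible-interval overlap
#'
#' Returns the posterior mean and 95% CI of the level means of the model's
#' (single) fixed factor for two levels, and whether the intervals are
#' disjoint — non-overlap is read as evidence that the level means differ.
#'
#' @param fit an [rc_lmm()] whose fixed part is `~ factor`.
#' @param level_a,level_b factor level names.
#' @return list with `ci_a`, `ci_b` (named numeric: mean, l95, u95) and
#'   logical `non_overlap`.
#' @export
compare_levels <- function(fit, level_a, level_b) {
  stopifnot(inherits(fit, "rc_lmm"))
  if (length(fit$xlevels) != 1L) {
    stop("compare_levels needs a model with exactly one fixed factor")
  }
  fac <- names(fit$xlevels)[1]
  levs <- fit$xlevels[[1]]
  for (l in c(level_a, level_b)) {
    if (!l %in% levs) stop(sprintf("unknown level '%s' of factor '%s'",
                                   l, fac))
  }
  level_draws <- function(l) {
    d <- fit$draws[, "(Intercept)"]
    cn <- paste0(fac, l)
    if (cn %in% colnames(fit$draws)) d <- d + fit$draws[, cn]
    d
  }
  ci <- function(d) c(mean = mean(d),
                      l95 = unname(stats::quantile(d, 0.025)),
                      u95 = unname(stats::quantile(d, 0.975)))
  ci_a <- ci(level_draws(level_a))
  ci_b <- ci(level_draws(level_b))
  list(ci_a = ci_a, ci_b = ci_b,
       non_overlap = ci_a[["l95"]] > ci_b[["u95"]] ||
                     ci_b[["l95"]] > ci_a[["u95"]])
}
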