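#' Pipeline configuration
#'
#' Bundles every knob of the simulate -> metrics -> densities ->
#' repeatability pipeline. Can be built in R or loaded from a YAML file
#' whose keys match the argument names.
#'
#' @param out_dir output directory for CSVs, the resolved config and the
#'   log; `NULL` keeps everything in memory.
#' @param n_groups number of simulated groups; default 25.
#' @param durations per-context trial durations (s); the pipeline default
#'   uses shortened trials (open 120, foraging 120, cover 120) so a full
#'   run stays interactive; pass `NULL` inside to use protocol durations.
#' @param smoothing list with `window` and `polyorder`.
#' @param thresholds list with `min_step` (mm) and `min_centroid_speed`
#'   (cm/s).
#' @param mcmc list with `nitt`, `burnin`, `thin`, `chains`.
#' @param first_trial_only across-context models use only the first trial
#'   per context (the primary analysis); when `FALSE` all trials enter with
#'   the same 4-level context factor.
#' @param sim a [sim_config()] used as the base simulator configuration.
#' @param seed master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = NULL, n_groups = 25,
                            durations = c(open = 120, foraging = 120,
                                          cover = 120),
                            smoothing = list(window = 15, polyorder = 3),
                            thresholds = list(min_step = 0.2,
                                              min_centroid_speed = 0.5),
                            mcmc = list(nitt = 5000, burnin = 1000,
                                        thin = 4, chains = 2),
                            first_trial_only = TRUE,
                            sim = sim_config(), seed = 1) {
  structure(list(out_dir = out_dir, n_groups = n_groups,
                 durations = durations, smoothing = smoothing,
                 thresholds = thresholds, mcmc = mcmc,
                 first_trial_only = first_trial_only, sim = sim,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys are [pipeline_config()] arguments (the `sim`
#'   entry holds [sim_config()] arguments).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- do.call(sim_config, sim_args)
  if (!is.null(raw$durations)) raw$durations <- unlist(raw$durations)
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Summarize every trial into tidy metric tables, splitting foraging trials
# at the depletion frame so the 4-level context factor emerges.
trial_metric_tables <- function(trials, cfg) {
  ind <- list(); grp <- list()
  for (tid in names(trials)) {
    tr <- trials[[tid]]$trajectory
    meta <- trials[[tid]]$metadata
    tr <- smooth_trajectory(fill_gaps(tr), cfg$smoothing$window,
                            cfg$smoothing$polyorder)
    windows <- if (meta$context == "foraging") {
      w <- split_foraging_trial(tr, meta)
      w[vapply(w, function(x) x[2] > x[1], logical(1))]  # drop empty halves
    } else list(full = NULL)
    for (w in names(windows)) {
      ctx4 <- switch(meta$context,
                     open = "open", cover = "cover",
                     foraging = paste0("foraging_", w))
      tm <- summarize_trial(tr, meta, windows[[w]],
                            min_step = cfg$thresholds$min_step,
                            min_centroid_speed =
                              cfg$thresholds$min_centroid_speed)
      tm$individual$context4 <- ctx4
      tm$group$context4 <- ctx4
      key <- paste(tid, w, sep = ".")
      ind[[key]] <- tm$individual
      grp[[key]] <- tm$group
    }
  }
  list(individual = do.call(rbind, c(ind, make.row.names = FALSE)),
       group = do.call(rbind, c(grp, make.row.names = FALSE)))
}

fit_table1_models <- function(ind, grp, cfg) {
  mc <- cfg$mcmc
  fit <- function(formula, data, random) {
    rc_lmm(formula, data, random = random, nitt = mc$nitt,
           burnin = mc$burnin, thin = mc$thin, chains = mc$chains,
           seed = cfg$seed)
  }
  lev <- intersect(c("open", "foraging_pre", "foraging_post", "cover"),
                   unique(ind$context4))   # only levels with data
  ind$context4 <- factor(ind$context4, lev)
  grp$context4 <- factor(grp$context4, lev)
  models <- list(
    speed = fit(median_speed ~ context4, ind,
                c("group_id", "individual_id")),
    centre_distance = fit(mean_centre_distance ~ context4, ind,
                          c("group_id", "individual_id")),
    leadership = fit(front_proportion ~ context4, ind,
                     c("group_id", "individual_id")),
    polarization = fit(median_polarization ~ context4, grp, "group_id"),
    leadership_structure = fit(leadership_variance ~ context4, grp,
                               "group_id"))
  models
}

table1_rows <- function(models) {
  rows <- list()
  for (resp in names(models)) {
    fit <- models[[resp]]
    vt <- posterior_table(fit)
    rc <- repeatability(fit)
    has_id <- "V_id" %in% fit$vnames
    rows[[resp]] <- data.frame(
      response = resp,
      v_group = vt["V_group", "mean"],
      v_group_l95 = vt["V_group", "l95"], v_group_u95 = vt["V_group", "u95"],
      v_id = if (has_id) vt["V_id", "mean"] else NA,
      v_res = vt["V_res", "mean"],
      r_group = rc$mean[rc$level == "group"],
      r_group_l95 = rc$l95[rc$level == "group"],
      r_group_u95 = rc$u95[rc$level == "group"],
      r_group_significant = rc$significant[rc$level == "group"],
      r_id = if (has_id) rc$mean[rc$level == "id"] else NA,
      r_id_l95 = if (has_id) rc$l95[rc$level == "id"] else NA,
      r_id_u95 = if (has_id) rc$u95[rc$level == "id"] else NA,
      r_id_significant = if (has_id) rc$significant[rc$level == "id"] else NA,
      max_psrf = max(fit$psrf[fit$vnames], na.rm = TRUE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

context_effect_table <- function(models) {
  rows <- list()
  for (resp in names(models)) {
    fit <- models[[resp]]
    levs <- fit$xlevels[[1]]
    prs <- utils::combn(levs, 2)
    for (k in seq_len(ncol(prs))) {
      cmp <- compare_levels(fit, prs[1, k], prs[2, k])
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, level_a = prs[1, k], level_b = prs[2, k],
        mean_a = cmp$ci_a[["mean"]], l95_a = cmp$ci_a[["l95"]],
        u95_a = cmp$ci_a[["u95"]],
        mean_b = cmp$ci_b[["mean"]], l95_b = cmp$ci_b[["l95"]],
        u95_b = cmp$ci_b[["u95"]],
        significantly_different = cmp$non_overlap)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

fit_within_context_models <- function(ind, cfg) {
  mc <- cfg$mcmc
  out <- list()
  for (ctx in c("foraging", "cover")) {
    sub <- if (ctx == "foraging") {
      ind[ind$context4 == "foraging_pre", ]    # pre-depletion behaviour only
    } else ind[ind$context == "cover", ]
    if (length(unique(sub$trial_number)) < 2L) next
    sub$trial <- factor(sub$trial_number)
    for (resp in c("median_speed", "mean_centre_distance",
                   "front_proportion")) {
      f <- stats::as.formula(paste(resp, "~ trial"))
      out[[paste(ctx, resp, sep = ".")]] <- rc_lmm(
        f, sub, random = c("group_id", "individual_id"),
        nitt = mc$nitt, burnin = mc$burnin, thin = mc$thin,
        chains = mc$chains, seed = cfg$seed)
    }
  }
  out
}

within_context_rows <- function(models) {
  if (!length(models)) return(NULL)
  rows <- lapply(names(models), function(nm) {
    rc <- repeatability(models[[nm]])
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(context = parts[1], response = parts[2],
               r_group = rc$mean[rc$level == "group"],
               r_group_l95 = rc$l95[rc$level == "group"],
               r_group_u95 = rc$u95[rc$level == "group"],
               r_group_significant = rc$significant[rc$level == "group"],
               r_id = rc$mean[rc$level == "id"],
               r_id_l95 = rc$l95[rc$level == "id"],
               r_id_u95 = rc$u95[rc$level == "id"])
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the group-assay experiment, computes trial metrics,
#' density maps, and the across- and within-context repeatability models,
#' and (when `config$out_dir` is set) writes every table as CSV together
#' with the resolved configuration and a log. The pipeline is a pure
#' function of `(config, seed)`: rerunning with the same configuration
#' reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @param trials optional pre-built list of `list(trajectory, metadata)`
#'   (e.g. from [read_trajectories()]); when `NULL` the experiment is
#'   simulated.
#' @return list of class `"shoal_pipeline"`: `metrics` (individual and
#'   group tables), `densities`, `table1` (across-context variance
#'   components and repeatability), `within_context`, `context_effects`,
#'   `models`, `truth`, `config`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL) {
  t0 <- Sys.time()
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- NULL
  if (is.null(trials)) {
    say("simulate: %d groups, seed %d", config$n_groups, config$seed)
    exp <- stage("simulate", simulate_experiment(
      config$sim, n_groups = config$n_groups,
      durations = config$durations, seed = config$seed))
    trials <- exp$trials
    truth <- exp$truth
  }
  say("metrics: %d trials", length(trials))
  metrics <- stage("metrics", trial_metric_tables(trials, config))
  say("densities")
  densities <- stage("density", {
    out <- list()
    for (ctx in unique(metrics$group$context4)) {
      tids <- unique(metrics$group$trial_id[metrics$group$context4 == ctx &
                                            metrics$group$trial_number == 1])
      tid <- tids[1]
      if (is.na(tid) || is.null(trials[[tid]])) next
      tr <- smooth_trajectory(fill_gaps(trials[[tid]]$trajectory),
                              config$smoothing$window,
                              config$smoothing$polyorder)
      out[[ctx]] <- list(
        neighbour = neighbour_density(tr, trials[[tid]]$metadata),
        speed_polarization = speed_polarization_density(tr))
    }
    out
  })
  ind <- metrics$individual
  grp <- metrics$group
  if (config$first_trial_only) {
    ind <- ind[ind$trial_number == 1, ]
    grp <- grp[grp$trial_number == 1, ]
  }
  say("repeatability: across-context models")
  models <- stage("repeatability", fit_table1_models(ind, grp, config))
  table1 <- table1_rows(models)
  ctx_fx <- context_effect_table(models)
  say("repeatability: within-context models")
  within <- stage("repeatability",
                  fit_within_context_models(metrics$individual, config))
  within_tab <- within_context_rows(within)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res <- structure(
    list(metrics = metrics, densities = densities, table1 = table1,
         within_context = within_tab, context_effects = ctx_fx,
         models = models, truth = truth, config = config, log = log),
    class = "shoal_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res)
  res
}

write_pipeline_outputs <- function(res) {
  dir <- res$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$metrics$individual,
                   file.path(dir, "trial_metrics_individual.csv"),
                   row.names = FALSE)
  utils::write.csv(res$metrics$group,
                   file.path(dir, "trial_metrics_group.csv"),
                   row.names = FALSE)
  utils::write.csv(res$table1, file.path(dir, "repeatability_table.csv"),
                   row.names = FALSE)
  if (!is.null(res$within_context)) {
    utils::write.csv(res$within_context,
                     file.path(dir, "within_context_repeatability.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$context_effects,
                   file.path(dir, "context_effects.csv"), row.names = FALSE)
  if (!is.null(res$truth)) {
    utils::write.csv(res$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  for (ctx in names(res$densities)) {
    write_density_map(res$densities[[ctx]]$neighbour,
                      file.path(dir, paste0("density_neighbour_", ctx,
                                            ".csv")))
    write_density_map(res$densities[[ctx]]$speed_polarization,
                      file.path(dir, paste0("density_speedpol_", ctx,
                                            ".csv")))
  }
  cfg <- res$config
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), file.path(dir, "resolved_config.yaml"))
  writeLines(res$log, file.path(dir, "pipeline.log"))
  writeLines(report(res), file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.shoal_pipeline <- function(x, ...) {
  cat(sprintf("<shoal_pipeline> %d trials, %d across-context estimates\n",
              length(unique(x$metrics$group$trial_id)), nrow(x$table1)))
  print(round(x$table1[, c("v_group", "v_id", "v_res", "r_group",
                           "r_id")], 4))
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Renders a markdown summary of a [run_pipeline()] result: context means
#' with 95% CIs and overlap verdicts, then the across-context repeatability
#' table. Every number equals the corresponding cell of the CSV outputs.
#'
#' @param results a `shoal_pipeline` object (or `NULL`/empty).
#' @return character vector of markdown lines.
#' @export
report <- function(results) {
  if (is.null(results) || is.null(results$table1) ||
      !nrow(results$table1)) {
    return("# Shoal pipeline report\n\nno models fitted")
  }
  t1 <- results$table1
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  lines <- c("# Shoal pipeline report", "",
             sprintf("Across-context models: %d", nrow(t1)), "",
             "## Across-context repeatability", "",
             paste("| response | V_group | V_id | V_res | R_C group",
                   "| R_C individual |"),
             "|---|---|---|---|---|---|")
  for (k in seq_len(nrow(t1))) {
    r <- t1[k, ]
    lines <- c(lines, sprintf(
      "| %s | %s [%s-%s] | %s | %s | %s [%s-%s]%s | %s |",
      r$response, fmt(r$v_group), fmt(r$v_group_l95), fmt(r$v_group_u95),
      if (is.na(r$v_id)) "-" else fmt(r$v_id), fmt(r$v_res),
      fmt(r$r_group), fmt(r$r_group_l95), fmt(r$r_group_u95),
      if (isTRUE(r$r_group_significant)) " *" else "",
      if (is.na(r$r_id)) "-" else sprintf("%s [%s-%s]%s", fmt(r$r_id),
        fmt(r$r_id_l95), fmt(r$r_id_u95),
        if (isTRUE(r$r_id_significant)) " *" else "")))
  }
  ce <- results$context_effects
  lines <- c(lines, "", "## Context effects (95% CI overlap)", "",
             "| response | A | B | mean A [CI] | mean B [CI] | different |",
             "|---|---|---|---|---|---|")
  for (k in seq_len(nrow(ce))) {
    r <- ce[k, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s [%s-%s] | %s [%s-%s] | %s |",
      r$response, r$level_a, r$level_b,
      fmt(r$mean_a), fmt(r$l95_a), fmt(r$u95_a),
      fmt(r$mean_b), fmt(r$l95_b), fmt(r$u95_b),
      if (isTRUE(r$significantly_different)) "yes" else "no"))
  }
  if (!is.null(results$within_context)) {
    wc <- results$within_context
    lines <- c(lines, "", "## Within-context repeatability", "",
               "| context | response | R_C group [CI] | R_C individual [CI] |",
               "|---|---|---|---|")
    for (k in seq_len(nrow(wc))) {
      r <- wc[k, ]
      lines <- c(lines, sprintf(
        "| %s | %s | %s [%s-%s]%s | %s [%s-%s] |",
        r$context, r$response, fmt(r$r_group), fmt(r$r_group_l95),
        fmt(r$r_group_u95),
        if (isTRUE(r$r_group_significant)) " *" else "",
        fmt(r$r_id), fmt(r$r_id_l95), fmt(r$r_id_u95)))
    }
  }
  lines
}
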