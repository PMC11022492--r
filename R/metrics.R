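#' Genetic trend as the regression of cohort means on birth year
#'
#' Ordinary least-squares slope of the cohort-mean breeding values (true or
#' estimated) on birth year, by default over cohorts 5-10 — the years after
#' the selection nucleus has closed. Applied identically to true breeding
#' values and to EBVs; the trend error of a replicate is
#' `(estimated - true) / true`.
#'
#' @param tab Data frame with columns `year`, `w`, `q` (one row per queen).
#' @param years Cohort years to include.
#' @return Named vector `c(w = slope, q = slope)`.
#' @export
genetic_trend <- function(tab, years = 5:10) {
  tab <- tab[tab$year %in% years, , drop = FALSE]
  if (length(unique(tab$year)) < 2L)
    stop("genetic trend needs at least two distinct cohort years")
  mw <- aggregate(cbind(w, q) ~ year, data = tab, FUN = mean)
  c(w = unname(coef(lm(w ~ year, data = mw))[2L]),
    q = unname(coef(lm(q ~ year, data = mw))[2L]))
}

#' Simulate, encode and fit one replicate of a scenario
#'
#' Runs the full pipeline for one replicate: simulation under the
#' scenario's mating design, re-encoding of the sire side under the
#' scenario's estimation model, relationship factor and sparse inverse,
#' AI-REML fit, and BLUP genetic trends.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Replicate seed.
#' @param scheme_overrides Named list of [scheme_config()] arguments to
#'   override (e.g. `list(n_families = 12L)`).
#' @param start,start_vg,maxit,tol Passed to [reml_fit()].
#' @param trend_years Cohort years for the genetic-trend regressions.
#' @param keep_fit Keep the full fit object in the result.
#' @return A list with `summary` (one-row data frame of estimates, relative
#'   errors, trend errors and convergence) and optionally `fit`.
#' @export
run_replicate_scenario <- function(scenario, seed, scheme_overrides = list(),
                                   start = c(5, 0, 5, 35), start_vg = 1,
                                   maxit = 200L, tol = 1e-8,
                                   trend_years = 5:10, keep_fit = FALSE) {
  params <- gene_params_preset(scenario$params_set)
  sch_args <- list(controlled_style = scenario$sim_controlled,
                   open_structure = if (scenario$set == "II") "TWO_SUBPOPS"
                                    else "HOMOGENEOUS")
  sch_args[names(scheme_overrides)] <- scheme_overrides
  scheme <- do.call(scheme_config, sch_args)
  if (scheme$open_structure == "TWO_SUBPOPS")
    params$alpha <- rep(sqrt(params$var_q) / 2, 2L)

  sim <- run_replicate(params, scheme, seed = seed)
  enc <- encode_scenario(sim, scenario)
  factor <- build_factor(enc$ped)
  ge <- switch(scenario$estim_open, O_FixedGroup = "fixed",
               O_RandGroup = "random", "none")
  model <- build_model(enc$perf, factor, group_effect = ge)
  fit <- reml_fit(model, factor, start = start, start_vg = start_vg,
                  maxit = maxit, tol = tol)

  trend_years <- intersect(trend_years, seq_len(scheme$n_years))
  if (length(trend_years) < 2L)       # short test schemes: use all cohorts
    trend_years <- seq_len(scheme$n_years)
  bq <- sim$queens[sim$queens$role == "BQ", ]
  tr_true <- genetic_trend(data.frame(year = bq$year, w = bq$bw, q = bq$bq),
                           trend_years)
  ebv <- ebv_table(fit, factor, enc$ped)
  ebv_bq <- ebv[match(enc$queen_map[bq$id], ebv$ped_id), ]
  tr_est <- genetic_trend(data.frame(year = bq$year, w = ebv_bq$ebv_w,
                                     q = ebv_bq$ebv_q), trend_years)
  trend_err <- ifelse(tr_true != 0, (tr_est - tr_true) / tr_true, NA_real_)

  est <- fit$estimates
  truth <- c(var_w = params$var_w, cov_wq = params$cov_wq,
             var_q = params$var_q, var_e = params$var_e)
  r_true <- if (params$var_w > 0 && params$var_q > 0)
    params$cov_wq / sqrt(params$var_w * params$var_q) else 0
  summary <- data.frame(
    scenario = scenario$id, seed = seed, converged = fit$converged,
    n_iter = fit$n_iter,
    var_w_hat = est[["var_w"]], cov_wq_hat = est[["cov_wq"]],
    var_q_hat = est[["var_q"]], var_e_hat = est[["var_e"]],
    var_g_hat = if ("var_g" %in% names(est)) est[["var_g"]] else NA_real_,
    r_wq_hat = fit$r_wq,
    rel_err_w = (est[["var_w"]] - truth[["var_w"]]) / truth[["var_w"]],
    rel_err_q = (est[["var_q"]] - truth[["var_q"]]) / truth[["var_q"]],
    rel_err_e = (est[["var_e"]] - truth[["var_e"]]) / truth[["var_e"]],
    r_wq_err = fit$r_wq - r_true,
    se_pred_w = fit$se_pred[["var_w"]], se_pred_q = fit$se_pred[["var_q"]],
    se_pred_wq = fit$se_pred[["cov_wq"]],
    trend_true_w = tr_true[["w"]], trend_true_q = tr_true[["q"]],
    trend_est_w = tr_est[["w"]], trend_est_q = tr_est[["q"]],
    trend_err_w = trend_err[["w"]], trend_err_q = trend_err[["q"]])
  out <- list(summary = summary)
  if (keep_fit) out$fit <- fit
  out
}

#' Replicate battery for a scenario
#'
#' Runs `n_rep` replicates (replicate `r` uses seed `base_seed + r`),
#' collecting per-replicate summaries; failures are logged and counted as
#' non-converged. Identical `base_seed` gives identical tables.
#'
#' @inheritParams run_replicate_scenario
#' @param n_rep Number of replicates.
#' @param base_seed Battery seed.
#' @param ... Passed to [run_replicate_scenario()].
#' @return A data frame of per-replicate summaries (class
#'   `bee_battery`).
#' @export
run_battery <- function(scenario, n_rep, base_seed, ...) {
  rows <- lapply(seq_len(n_rep), function(r) {
    res <- tryCatch(run_replicate_scenario(scenario, seed = base_seed + r,
                                           ...)$summary,
                    error = function(e) {
                      warning("replicate ", r, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) {
      res <- data.frame(scenario = scenario$id, seed = base_seed + r,
                        converged = FALSE, n_iter = NA_integer_)
    }
    res
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bee_battery", "data.frame")
  out
}

#' Aggregate a battery into the scenario summary statistics
#'
#' Relative bias is the mean across converged replicates of
#' `(estimate - truth)/truth`, in percent; relative SE is the standard
#' deviation of the same quantity, in percent; strong deviations are
#' replicates whose estimate differs from the truth by more than 20%. The
#' bias of the estimated genetic correlation is reported in absolute units
#' (the true correlation may be zero). Trend errors are means of
#' `(estimated - true)/true` in percent. Non-converged replicates are
#' excluded from all statistics but reported as a rate.
#'
#' @param battery A [run_battery()] result (rows may pool multiple
#'   scenarios; aggregation is per scenario).
#' @return One row per scenario with bias/SE/strong-deviation columns.
#' @export
aggregate_battery <- function(battery) {
  one <- function(b) {
    conv <- b[which(b$converged), , drop = FALSE]
    pct <- function(x) 100 * mean(x, na.rm = TRUE)
    ## root-mean-square deviation from the mean (population SD): at battery
    ## scale indistinguishable from the sample SD, and exact for the
    ## two-replicate worked examples
    pctsd <- function(x) {
      x <- x[!is.na(x)]
      100 * sqrt(mean((x - mean(x))^2))
    }
    strong <- function(x) 100 * mean(abs(x) > 0.2, na.rm = TRUE)
    data.frame(
      scenario = b$scenario[1L], n_rep = nrow(b),
      conv_rate = mean(b$converged, na.rm = TRUE),
      bias_w = pct(conv$rel_err_w), se_w = pctsd(conv$rel_err_w),
      strong_w = strong(conv$rel_err_w),
      bias_q = pct(conv$rel_err_q), se_q = pctsd(conv$rel_err_q),
      strong_q = strong(conv$rel_err_q),
      bias_e = pct(conv$rel_err_e), se_e = pctsd(conv$rel_err_e),
      bias_r = mean(conv$r_wq_err, na.rm = TRUE),
      se_r = sd(conv$r_wq_err, na.rm = TRUE),
      trend_err_w = pct(conv$trend_err_w),
      trend_err_q = pct(conv$trend_err_q),
      mean_pred_se_w = mean(conv$se_pred_w, na.rm = TRUE),
      mean_pred_se_q = mean(conv$se_pred_q, na.rm = TRUE),
      realized_se_w = sd(conv$var_w_hat, na.rm = TRUE),
      realized_se_q = sd(conv$var_q_hat, na.rm = TRUE))
  }
  parts <- split(as.data.frame(battery), battery$scenario)
  out <- do.call(rbind, lapply(parts, one))
  rownames(out) <- NULL
  out
}

#' One-command scenario run
#'
#' Orchestrates battery execution and aggregation for a named scenario and
#' optionally writes the per-replicate table, the scenario summary and a
#' reproducibility manifest to a directory.
#'
#' @inheritParams run_battery
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return A list with `battery`, `table` and `manifest`.
#' @export
run_scenario <- function(scenario, n_rep, base_seed, scheme_overrides = list(),
                         out_dir = NULL, ...) {
  battery <- run_battery(scenario, n_rep, base_seed,
                         scheme_overrides = scheme_overrides, ...)
  table <- aggregate_battery(battery)
  manifest <- data.frame(
    key = c("scenario", "n_rep", "base_seed", "overrides", "package",
            "version"),
    value = c(scenario$id, n_rep, base_seed,
              paste(names(scheme_overrides), unlist(scheme_overrides),
                    sep = "=", collapse = ";"),
              "apisim", as.character(utils::packageVersion("apisim"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(battery, file.path(out_dir,
                                   paste0(scenario$id, "_replicates.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(table, file.path(out_dir, paste0(scenario$id, "_table.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(manifest, file.path(out_dir,
                                    paste0(scenario$id, "_manifest.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(battery = battery, table = table, manifest = manifest)
}
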