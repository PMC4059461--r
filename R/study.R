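#' Simulation study cell
#'
#' One factorial cell of the bias/RMSE/coverage study: a scenario preset, a
#' sample size, independent (`gamma1 = 0`) or covariate-dependent
#' (`gamma1 = 1`) censoring, a target censoring rate among observations
#' before the truncation time, and the truncation quantile of the marginal
#' event-time distribution.
#'
#' @param scenario preset name (`"CR1"`, `"CR2"`) or a [sim_scenario()].
#' @param n cohort size per replication.
#' @param gamma1 censoring log hazard ratio.
#' @param target_cens target fraction of right-censored observations among
#'   those observed before `t`, in `[0, 1)`.
#' @param trunc_p truncation quantile of the marginal time distribution
#'   (0.75 targets `q75`).
#' @param n_reps number of simulation replications (>= 2).
#' @param n_boot bootstrap resamples per replication for bootstrap coverage;
#'   0 disables the bootstrap.
#' @param seed integer seed for the cell; replication streams are derived
#'   from it.
#' @return an object of class `study_cell`.
#' @export
study_cell <- function(scenario = "CR1", n = 1000, gamma1 = 0,
                       target_cens = 0.25, trunc_p = 0.75,
                       n_reps = 1000, n_boot = 0, seed = 1) {
  if (is.character(scenario)) scenario <- sim_scenario(scenario)
  if (!inherits(scenario, "sim_scenario"))
    crc_config_error("scenario must be a preset name or a sim_scenario")
  if (n < 2) crc_validation_error("n must be >= 2")
  if (n_reps < 2) crc_validation_error("n_reps must be >= 2")
  if (target_cens < 0 || target_cens >= 1)
    crc_validation_error("target_cens must be in [0, 1)")
  if (trunc_p <= 0 || trunc_p >= 1)
    crc_validation_error("trunc_p must be in (0, 1)")
  structure(list(scenario = scenario, n = as.integer(n), gamma1 = gamma1,
                 target_cens = target_cens, trunc_p = trunc_p,
                 n_reps = as.integer(n_reps), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "study_cell")
}

#' Run one simulation study cell
#'
#' For each replication: simulate an uncensored sample, censor it at the
#' calibrated rate, and compute the requested estimators of `C1(t)` at
#' `t` = the `trunc_p` marginal quantile, using the generator's marker as
#' prediction. The KM-IPCW estimator additionally gets an asymptotic Wald
#' interval; with `n_boot > 0` every estimator gets a percentile bootstrap
#' interval. The cell truth is computed once by quadrature. Replications in
#' which an estimator is undefined (no evaluable pairs) are excluded and
#' counted; more than 5 percent of failures aborts the cell.
#'
#' @param cell a [study_cell()].
#' @param estimators subset of `c("naive", "ipcw_km", "ipcw_cox")`.
#' @param wald compute the asymptotic Wald interval for the KM-IPCW
#'   estimator in every replication (needed for SE/coverage summaries; skip
#'   for bias/RMSE-only runs).
#' @param level confidence level for coverage.
#' @param calibrate_mc_size Monte Carlo size for censoring-rate calibration.
#' @param verbose print a line per 100 replications.
#' @return an object of class `sim_study_result`: the cell, `t`, `truth`,
#'   the calibrated `lambda0_cens`, a per-estimator summary data frame
#'   (`bias100`, `rmse100`, `emp_sd`, `mc_se_bias100`, mean SEs and
#'   coverage where available) and per-replication estimates.
#' @export
run_cell <- function(cell, estimators = c("naive", "ipcw_km", "ipcw_cox"),
                     wald = TRUE, level = 0.95, calibrate_mc_size = 200000,
                     verbose = FALSE) {
  stopifnot(inherits(cell, "study_cell"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  scen <- cell$scenario
  scen$gamma1 <- cell$gamma1
  tpt <- marginal_quantile(scen, cell$trunc_p)
  truth <- true_concordance(scen, tpt, method = "quadrature")$value
  scen$lambda0_cens <- if (cell$target_cens > 0)
    calibrate_censoring_rate(scen, tpt, cell$target_cens,
                             mc_size = calibrate_mc_size,
                             seed = derive_seed(cell$seed, 999999L))
  else 0

  nr <- cell$n_reps
  est <- matrix(NA_real_, nr, length(estimators),
                dimnames = list(NULL, estimators))
  ase <- rep(NA_real_, nr)
  wald_cover <- rep(NA, nr)
  boot_cover <- matrix(NA, nr, length(estimators),
                       dimnames = list(NULL, estimators))
  boot_se <- rep(NA_real_, nr)
  failures <- 0L

  for (r in seq_len(nr)) {
    rep_seed <- derive_seed(cell$seed, r)
    s <- simulate_uncensored(scen, cell$n, rep_seed)
    coh <- apply_censoring(s, scen, rep_seed)
    M <- coh$covariates$x
    ok <- TRUE
    for (e in estimators) {
      v <- tryCatch(estimate_once(coh, M, tpt, 1L, e, "strict")$value,
                    crcindex_error = function(err) NA_real_)
      est[r, e] <- v
      if (is.na(v)) ok <- FALSE
    }
    if (!ok) { failures <- failures + 1L; next }
    if (wald && "ipcw_km" %in% estimators) {
      inf <- tryCatch(asymptotic_se_km(coh, M, tpt, level = level),
                      crcindex_error = function(err) NULL)
      if (!is.null(inf)) {
        ase[r] <- inf$se
        wald_cover[r] <- truth >= inf$ci[1] && truth <= inf$ci[2]
      }
    }
    if (cell$n_boot > 0) {
      for (e in estimators) {
        b <- tryCatch(
          bootstrap_ci(coh, M, tpt, estimator = e, n_boot = cell$n_boot,
                       level = level, seed = derive_seed(rep_seed, 555L)),
          crcindex_error = function(err) NULL)
        if (!is.null(b)) {
          boot_cover[r, e] <- truth >= b$ci[1] && truth <= b$ci[2]
          if (e == "ipcw_km") boot_se[r] <- b$se
        }
      }
    }
    if (verbose && r %% 100 == 0)
      message(sprintf("  replication %d/%d", r, nr))
  }
  if (failures > 0.05 * nr)
    crc_fit_error(sprintf("cell failed: %d/%d replications had no evaluable pairs",
                          failures, nr))

  summarise <- function(e) {
    v <- est[, e]
    v <- v[!is.na(v)]
    data.frame(
      estimator = e,
      n_used = length(v),
      bias100 = 100 * mean(v - truth),
      rmse100 = 100 * sqrt(mean((v - truth)^2)),
      emp_sd = sd(v),
      mc_se_bias100 = 100 * sd(v) / sqrt(length(v)),
      mean_asymptotic_se = if (e == "ipcw_km" && wald) mean(ase, na.rm = TRUE) else NA_real_,
      wald_coverage_pct = if (e == "ipcw_km" && wald) 100 * mean(wald_cover, na.rm = TRUE) else NA_real_,
      mean_boot_se = if (e == "ipcw_km" && cell$n_boot > 0)
        mean(boot_se, na.rm = TRUE) else NA_real_,
      boot_coverage_pct = if (cell$n_boot > 0)
        100 * mean(boot_cover[, e], na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, lapply(estimators, summarise))
  structure(list(cell = cell, t = tpt, truth = truth,
                 lambda0_cens = scen$lambda0_cens,
                 summary = summary, estimates = est,
                 failed_reps = failures),
            class = "sim_study_result")
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat(sprintf("<sim_study_result> %s, n = %d, gamma1 = %g, %.0f%% censored before t\n",
              x$cell$scenario$preset %||% "custom", x$cell$n,
              x$cell$gamma1, 100 * x$cell$target_cens))
  cat(sprintf("  t = %.4f (p = %.2f), truth C1(t) = %.4f, lambda0_cens = %.4f, reps = %d (%d failed)\n",
              x$t, x$cell$trunc_p, x$truth, x$lambda0_cens,
              x$cell$n_reps, x$failed_reps))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run a full simulation study from a configuration
#'
#' Orchestrates a set of [study_cell()]s: per-cell seeds are derived from
#' the master seed by the cell's position (a counter-based scheme, so adding
#' cells never perturbs existing ones), each cell is run with [run_cell()],
#' and two summary tables are assembled — a bias/RMSE table and an
#' SE/coverage table. With `out_dir` set, the tables are written as TSV, the
#' full results as JSON, and a timing log as plain text.
#'
#' @param config a list (or path to a JSON file) with elements `seed`,
#'   optional defaults `n_reps`, `n_boot`, `trunc_p`, and `cells`: a list of
#'   cell specifications with fields `scenario`, `n`, `gamma1`,
#'   `target_cens` and optional overrides.
#' @param out_dir optional output directory.
#' @param ... passed to [run_cell()].
#' @return invisibly, a list with `results` (per-cell
#'   `sim_study_result`s), `bias_table` and `coverage_table`.
#' @export
run_study <- function(config, out_dir = NULL, ...) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$cells) || !length(config$cells))
    crc_config_error("config must contain a non-empty 'cells' list")
  master_seed <- config$seed %||% 1L
  cells_spec <- config$cells
  if (is.data.frame(cells_spec))
    cells_spec <- split(cells_spec, seq_len(nrow(cells_spec)))

  t0 <- Sys.time()
  results <- vector("list", length(cells_spec))
  for (k in seq_along(cells_spec)) {
    spec <- as.list(cells_spec[[k]])
    cell <- study_cell(
      scenario = spec$scenario %||% "CR1",
      n = spec$n %||% 1000,
      gamma1 = spec$gamma1 %||% 0,
      target_cens = spec$target_cens %||% 0.25,
      trunc_p = spec$trunc_p %||% config$trunc_p %||% 0.75,
      n_reps = spec$n_reps %||% config$n_reps %||% 1000,
      n_boot = spec$n_boot %||% config$n_boot %||% 0,
      seed = spec$seed %||% derive_seed(master_seed, k)
    )
    results[[k]] <- run_cell(cell, ...)
  }

  cell_id <- function(res) data.frame(
    scenario = res$cell$scenario$preset %||% "custom",
    n = res$cell$n, gamma1 = res$cell$gamma1,
    censored_pct = 100 * res$cell$target_cens,
    t = res$t, truth = res$truth, stringsAsFactors = FALSE)
  bias_table <- do.call(rbind, lapply(results, function(res)
    cbind(cell_id(res),
          res$summary[c("estimator", "bias100", "rmse100", "mc_se_bias100")])))
  coverage_table <- do.call(rbind, lapply(results, function(res)
    cbind(cell_id(res),
          res$summary[c("estimator", "emp_sd", "mean_asymptotic_se",
                        "mean_boot_se", "wald_coverage_pct",
                        "boot_coverage_pct")])))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(bias_table, file.path(out_dir, "bias_rmse.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(coverage_table, file.path(out_dir, "se_coverage.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config = config, bias = bias_table, coverage = coverage_table,
           elapsed_sec = elapsed),
      file.path(out_dir, "study.json"), digits = NA, dataframe = "rows")
    writeLines(sprintf("%d cells in %.1f s", length(results), elapsed),
               file.path(out_dir, "study.log"))
  }
  invisible(list(results = results, bias_table = bias_table,
                 coverage_table = coverage_table, elapsed_sec = elapsed))
}
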