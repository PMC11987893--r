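#' Run the full calibration-and-evaluation pipeline
#'
#' Chains the whole grading-device workflow on a synthetic population:
#'
#' 1. **simulate** — generate a carcass population
#'    ([generate_population()]);
#' 2. **select** — draw the stratified dissection sample and
#'    total-dissection subsample ([select_sample()]);
#' 3. **dissect** — realize cut weights for every selected carcass,
#'    compute partial-dissection LMP for all of them and total-dissection
#'    LMP for the subsample, estimate the scaling factor on the subsample
#'    ([compute_sf()]) and form the bias-corrected reference LMP;
#' 4. **calibrate** — fit the prediction equation by PLS and
#'    cross-validate its RMSEP ([calibrate()]);
#' 5. **grade & compare** — apply the old equation and the newly fitted
#'    (or configured) equation to the whole population and summarize the
#'    class-structure consequences ([compare_equations()]).
#'
#' Per-stage seeds are derived deterministically from `config$seed`, so a
#' fixed configuration yields byte-identical results. When `out_dir` is
#' given, per-stage CSV artifacts and a JSON report are written there.
#'
#' @param config a [pipeline_config()] (or the result of
#'   [read_pipeline_config()]).
#' @param out_dir optional output directory for stage artifacts.
#' @param verbose emit one progress line per stage.
#' @return an object of class `pipeline_summary`: a list with the
#'   population, selection, dissection table, scaling factor, calibration
#'   report and equation comparison, plus stage record counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage_log <- list()
  tick <- function(stage, n) {
    dt <- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
    stage_log[[stage]] <<- list(records = n, seconds = round(dt, 3))
    say("[%s] %d records (%.2fs)", stage, n, dt)
  }

  # 1. simulate
  pop <- generate_population(config$population, seed = config$seed)
  tick("simulate", nrow(pop))

  # 2. select
  sel <- select_sample(pop, config$plan, seed = config$seed + 1L)
  tick("select", nrow(sel$selected))
  if (nrow(sel$shortfalls))
    say("  shortfalls in %d cell(s), total deficit %d",
        nrow(sel$shortfalls), sum(sel$shortfalls$deficit))

  # 3. dissect
  dis <- sel$selected
  if (nrow(dis) == 0L)
    stop("stage 'dissect' failed: no carcasses selected", call. = FALSE)
  ypd <- numeric(nrow(dis))
  ytd <- rep(NA_real_, nrow(dis))
  for (i in seq_len(nrow(dis))) {
    cw <- generate_cut_weights(dis[i, ], seed = config$seed + 1000L + i)
    ypd[i] <- compute_ypd(cw)
    if (dis$in_subsample[i])
      ytd[i] <- compute_ytd(cw$total_lean_weight, cw$half_carcass_weight)
  }
  dis$ypd <- ypd
  dis$ytd <- ytd
  sub <- dis$in_subsample
  if (!any(sub))
    stop("stage 'dissect' failed: empty total-dissection subsample",
         call. = FALSE)
  sf <- compute_sf(dis$ytd[sub], dis$ypd[sub], round_to = config$sf_round)
  dis$lmp_ref <- apply_sf(dis$ypd, sf)
  tick("dissect", nrow(dis))

  # 4. calibrate
  cal <- calibrate(data.frame(f2 = dis$f2_mm, m2 = dis$m2_mm,
                              lmp_ref = dis$lmp_ref),
                   n_components = config$n_components,
                   folds = config$folds, limit = config$limit,
                   seed = config$seed + 2L)
  tick("calibrate", cal$n)

  # 5. grade & compare
  eq_new <- if (is.null(config$eq_new)) cal$equation else
    resolve_equation(config$eq_new, "2023")
  cmp <- compare_equations(pop, config$eq_old, eq_new)
  tick("compare", cmp$n)

  out <- structure(list(
    config = config,
    population = pop,
    selection = sel,
    dissection = dis,
    scaling_factor = sf,
    calibration = cal,
    comparison = cmp,
    stage_log = stage_log
  ), class = "pipeline_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_carcass_csv(pop, file.path(out_dir, "population.csv"))
    write_carcass_csv(dis, file.path(out_dir, "dissection_sample.csv"))
    jsonlite::write_json(pipeline_report(out), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE,
                         path = file.path(out_dir, "report.json"))
    say("artifacts written to %s", out_dir)
  }
  out
}

# machine-readable report of the pipeline's key statistics
pipeline_report <- function(x) {
  stopifnot(inherits(x, "pipeline_summary"))
  list(
    n_population = nrow(x$population),
    n_selected = nrow(x$selection$selected),
    n_subsample = sum(x$dissection$in_subsample),
    shortfalls = x$selection$shortfalls,
    scaling_factor = list(value = x$scaling_factor$value,
                          ytd_mean = x$scaling_factor$ytd_mean,
                          ypd_mean = x$scaling_factor$ypd_mean),
    equation = list(intercept = x$calibration$equation$intercept,
                    coef_f2 = x$calibration$equation$coef_f2,
                    coef_m2 = x$calibration$equation$coef_m2),
    rmsep = x$calibration$rmsep,
    authorized = x$calibration$authorized,
    mean_lmp_old = x$comparison$mean_lmp_old,
    mean_lmp_new = x$comparison$mean_lmp_new,
    mean_shift = x$comparison$mean_shift,
    class_shares_old = stats::setNames(as.list(x$comparison$structure_old$shares),
                                       x$comparison$structure_old$labels),
    class_shares_new = stats::setNames(as.list(x$comparison$structure_new$shares),
                                       x$comparison$structure_new$labels)
  )
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Grading-device calibration pipeline\n")
  cat(sprintf("  population: %s carcasses; selected %d (%d shortfall(s))\n",
              format(nrow(x$population), big.mark = ","),
              nrow(x$selection$selected),
              sum(x$selection$shortfalls$deficit)))
  cat(sprintf("  scaling factor: %.2f (YTD %.2f / YPD %.2f, n = %d)\n",
              x$scaling_factor$value, x$scaling_factor$ytd_mean,
              x$scaling_factor$ypd_mean, x$scaling_factor$n_subsample))
  cat("  ")
  print(x$calibration$equation)
  cat(sprintf("  RMSEP = %.3f pp -> %s\n", x$calibration$rmsep,
              if (x$calibration$authorized) "authorized" else
                "not authorized"))
  cat(sprintf("  population mean LMP: %.2f%% (old eq) vs %.2f%% (new eq), shift %+.2f pp\n",
              x$comparison$mean_lmp_old, x$comparison$mean_lmp_new,
              x$comparison$mean_shift))
  invisible(x)
}
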