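#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates generate -> simulate -> analyze -> report. The configuration
#' is a YAML file or a nested list with (all optional) sections:
#' \describe{
#'   \item{seed}{integer master seed (default 1); every stochastic stage
#'     derives its own seed from it and records it in the manifest.}
#'   \item{output_dir}{directory for stage outputs (required).}
#'   \item{connectivity_csv}{path to an existing connectivity matrix; when
#'     given, the circuit generator is skipped and only wiring statistics are
#'     computed (no simulation).}
#'   \item{circuit}{fields of [circuit_spec()].}
#'   \item{morphology}{fields of [morphology_spec()].}
#'   \item{membrane}{`preset` or explicit `r_m`/`c_m`/`r_a`/`e_rest`.}
#'   \item{synapse}{fields of [synapse_params()].}
#'   \item{simulate}{logical: run the EPSP stage (default `TRUE` when the
#'     circuit is generated).}
#'   \item{resample}{logical: run the shuffle control (default same).}
#'   \item{tasks}{`NULL` to skip, or a list with `conditions`, `n_train`,
#'     `n_test`.}
#' }
#'
#' @param config Path to a YAML file or a list.
#' @return Invisibly, a list with the stage results and the manifest. Files
#'   written: `connectivity.csv`, `connection_stats.csv`, `contributions.csv`,
#'   `summary.json`, `manifest.json`, and when enabled
#'   `epsp_connections.csv`, `shuffle_control.csv`, `task_results.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) abort("config$output_dir is required")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  out_file <- function(f) file.path(config$output_dir, f)
  manifest_env <- new.env(parent = emptyenv())
  manifest_env$stages <- list()
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed (seed ", seed, "): ",
                   conditionMessage(e)))
    })
  }

  # --- connectivity ----------------------------------------------------------
  generated <- is.null(config$connectivity_csv)
  table <- stage("connectivity", {
    if (generated) {
      cs <- do.call(circuit_spec,
                    c(config$circuit %||% list(),
                      if (is.null(config$circuit$seed)) list(seed = seed)))
      manifest_env$stages$circuit <- unclass(cs)
      generate_circuit(cs)
    } else {
      manifest_env$stages$connectivity_csv <- config$connectivity_csv
      load_connectivity(config$connectivity_csv)
    }
  })
  write_connectivity(table, out_file("connectivity.csv"))
  stats <- connection_stats(table)
  readr::write_csv(stats, out_file("connection_stats.csv"))
  contrib <- normalized_contributions(table, "per_antenna")
  readr::write_csv(contrib, out_file("contributions.csv"))
  ic <- ipsi_contra_comparison(table)
  lr <- left_right_totals(table)
  summary <- list(
    n_connections = stats$n_connections,
    mean_synapses_per_connection = stats$mean_synapses,
    contribution_cv = contribution_cv(table),
    ipsi_surplus_pct_grand = ic$surplus_pct_grand,
    right_vs_left_pct = lr$right_vs_left_pct
  )
  results$table <- table
  results$connection_stats <- stats

  do_sim <- isTRUE(config$simulate %||% generated)
  do_resample <- isTRUE(config$resample %||% generated)
  if (!generated) do_sim <- isTRUE(config$simulate)

  if (do_sim || do_resample || !is.null(config$tasks)) {
    models <- stage("models", {
      ms <- do.call(morphology_spec, config$morphology %||% list())
      mb <- do.call(membrane_params, config$membrane %||% list())
      manifest_env$stages$morphology <- unclass(ms)
      build_circuit_models(table, ms, mb, seed = seed + 17L)
    })
    syn <- do.call(synapse_params, config$synapse %||% list())
    results$models <- models
  }

  if (do_sim) {
    epsp <- stage("simulate", {
      purrr::map_dfr(models, function(m) {
        dplyr::mutate(
          measure_connections(m$model, m$sites, syn),
          pn_id = m$pn_id, .before = 1)
      })
    })
    readr::write_csv(epsp, out_file("epsp_connections.csv"))
    summary$mean_uepsp_mv <- mean(epsp$uepsp_mv)
    summary$mean_efficacy <- mean(epsp$efficacy)
    results$epsp <- epsp
  }

  if (do_resample) {
    shuf <- stage("resample", {
      m <- models[[1]]
      ipsi <- m$sites[m$sites$orn_side == m$side, ]
      shuffle_control(m$model, ipsi, syn,
                      n_shuffles = config$n_shuffles %||% 100,
                      seed = seed + 29L)
    })
    readr::write_csv(shuf, out_file("shuffle_control.csv"))
    results$shuffle_control <- shuf
  }

  if (!is.null(config$tasks)) {
    tk <- config$tasks
    task_res <- stage("tasks", {
      dplyr::bind_rows(
        run_detection_task(models, table,
                           conditions = tk$conditions %||% c(14, 17, 20),
                           wiring = "real",
                           n_train = tk$n_train %||% 250,
                           n_test = tk$n_test %||% 250,
                           syn = syn, seed = seed + 41L),
        run_detection_task(models, table,
                           conditions = tk$conditions %||% c(14, 17, 20),
                           wiring = "equalized",
                           n_train = tk$n_train %||% 250,
                           n_test = tk$n_test %||% 250,
                           syn = syn, seed = seed + 41L)
      )
    })
    readr::write_csv(task_res, out_file("task_results.csv"))
    results$tasks <- task_res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glomsim")),
    seed = seed,
    stages = manifest_env$stages
  )
  jsonlite::write_json(summary, out_file("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(manifest, out_file("manifest.json"), auto_unbox = TRUE)
  results$summary <- summary
  results$manifest <- manifest
  invisible(results)
}
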