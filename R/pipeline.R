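# End-to-end pipeline: ingest -> preprocess -> pair -> fit -> bootstrap ->
# zone summary, with a row-count run log at every exclusion step and a
# report bundle (paired-epoch CSV, fit JSON, zone CSV, Bland-Altman plot).

#' Pipeline configuration
#'
#' @param epoch_s Epoch length, seconds. Default 5.
#' @param jump_threshold,return_tolerance Spike-filter settings
#'   (beats/min). Defaults 10 and 5.
#' @param clock_offset_s Clock offset added to the index stream before
#'   epoching, seconds. Default 0.
#' @param with_ar1 Model AR(1) residual correlation in the agreement fit?
#'   Default `FALSE`.
#' @param n_bootstrap Bootstrap replicates for the LoA confidence
#'   intervals. Default 1000.
#' @param weighting MAE/MAPE weighting, `"participant_averaged"` or
#'   `"pooled"`. Default `"participant_averaged"`.
#' @param seed Integer seed for the bootstrap. Default 1.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(epoch_s = 5, jump_threshold = 10,
                            return_tolerance = 5, clock_offset_s = 0,
                            with_ar1 = FALSE, n_bootstrap = 1000,
                            weighting = c("participant_averaged", "pooled"),
                            seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(epoch_s > 0, jump_threshold > 0, return_tolerance >= 0,
            is.finite(clock_offset_s), n_bootstrap >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full agreement pipeline
#'
#' Reads the two device streams and the participant table, filters spike
#' artefacts from the criterion stream, epochs both streams onto the
#' shared absolute grid, pairs them, fits the repeated-measures
#' Bland-Altman model with bootstrap LoA intervals, and summarises error
#' by intensity zone. With `out_dir` set, writes `paired_epochs.csv`,
#' `agreement_fit.json`, `zone_summary.csv`, `bland_altman.svg`, and
#' `run_log.csv`; on any stage failure, partial outputs are removed.
#'
#' @param index_csv,criterion_csv,participants_csv Input CSV paths
#'   (device_io schemas). `criterion_csv` may be a heart-rate stream or an
#'   R-R interval stream (`criterion_format = "rr"`).
#' @param out_dir Optional output directory for the report bundle.
#' @param config A [pipeline_config()].
#' @param criterion_format `"hr"` or `"rr"`.
#' @return A list: `paired` (epoch table with zones), `fit`
#'   (`hr_agreement` with bootstrap CIs filled in), `zones` (zone summary
#'   tibble), `overall_error` (both weightings), `run_log` (row counts per
#'   stage).
#' @export
run_pipeline <- function(index_csv, criterion_csv, participants_csv,
                         out_dir = NULL, config = pipeline_config(),
                         criterion_format = c("hr", "rr")) {
  criterion_format <- match.arg(criterion_format)
  log_rows <- list()
  note <- function(stage, rows_in, rows_out) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, rows_in = rows_in, rows_out = rows_out,
      rows_removed = rows_in - rows_out)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(bundle_paths(out_dir))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)), parent = e)
    })
  }

  participants <- run_stage("ingest", read_participants_csv(participants_csv))
  index_raw <- run_stage("ingest", read_hr_csv(index_csv, "index"))
  criterion_raw <- run_stage("ingest", {
    if (criterion_format == "rr") {
      rr <- read_rr_csv(criterion_csv)
      rr_to_hr(rr) |> dplyr::mutate(device_role = "criterion")
    } else {
      read_hr_csv(criterion_csv, "criterion")
    }
  })

  filtered <- run_stage("artifact_filter", suppressMessages(
    remove_spike_artifacts(criterion_raw, config$jump_threshold,
                           config$return_tolerance)))
  note("criterion_artifact_filter", nrow(criterion_raw), nrow(filtered))

  shifted <- run_stage("clock_offset",
                       apply_clock_offset(index_raw, config$clock_offset_s))

  index_epochs <- run_stage("epoching", epoch_aggregate(shifted, config$epoch_s))
  criterion_epochs <- run_stage("epoching", epoch_aggregate(filtered, config$epoch_s))
  note("index_epoching", nrow(shifted), nrow(index_epochs))
  note("criterion_epoching", nrow(filtered), nrow(criterion_epochs))

  paired <- run_stage("pairing", pair_epochs(index_epochs, criterion_epochs))
  note("pairing", max(nrow(index_epochs), nrow(criterion_epochs)), nrow(paired))

  paired <- run_stage("zones", add_zones(paired, participants))

  fit <- run_stage("agreement_fit", fit_agreement(paired, with_ar1 = config$with_ar1))
  boot <- run_stage("bootstrap", suppressMessages(
    cluster_bootstrap_loa(paired, n_replicates = config$n_bootstrap,
                          seed = config$seed, with_ar1 = config$with_ar1)))
  fit$loa_lower_ci <- boot$loa_lower_ci
  fit$loa_upper_ci <- boot$loa_upper_ci

  zones <- run_stage("zone_summary",
                     zone_summary(paired, participants, weighting = config$weighting))
  overall <- dplyr::bind_rows(
    error_summary(paired, "participant_averaged"),
    error_summary(paired, "pooled")
  )
  run_log <- dplyr::bind_rows(log_rows)

  result <- list(paired = paired, fit = fit, zones = zones,
                 overall_error = overall, run_log = run_log,
                 config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- bundle_paths(out_dir)
    write_paired_epochs(paired, paths[["paired"]])
    jsonlite::write_json(fit_report(fit, config), paths[["fit"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(zones, paths[["zones"]])
    readr::write_csv(run_log, paths[["log"]])
    render_bland_altman(paired, fit, paths[["plot"]])
  }
  result
}

bundle_paths <- function(out_dir) {
  c(paired = file.path(out_dir, "paired_epochs.csv"),
    fit = file.path(out_dir, "agreement_fit.json"),
    zones = file.path(out_dir, "zone_summary.csv"),
    log = file.path(out_dir, "run_log.csv"),
    plot = file.path(out_dir, "bland_altman.svg"))
}

# serialisable fit report with config echo
fit_report <- function(fit, config) {
  list(
    mean_bias = fit$mu,
    mean_bias_ci = fit$mu_ci,
    tau2 = fit$tau2,
    sigma2 = fit$sigma2,
    phi = if (isTRUE(is.finite(fit$phi))) fit$phi else NULL,
    total_sd = fit$total_sd,
    loa_lower = fit$loa_lower,
    loa_upper = fit$loa_upper,
    loa_lower_ci = fit$loa_lower_ci,
    loa_upper_ci = fit$loa_upper_ci,
    n_epochs = fit$n_epochs,
    n_participants = fit$n_participants,
    degenerate = fit$degenerate,
    tau2_truncated = fit$tau2_truncated,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("hragree"))
  )
}

#' Render a Bland-Altman plot to a file
#'
#' Writes the [plot_bland_altman()] figure as SVG (via `svg()`) or PNG,
#' chosen from the file extension.
#'
#' @param table Paired-epoch tibble.
#' @param fit An `hr_agreement` object.
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Device size in inches. Defaults 7 x 5.
#' @return `path`, invisibly.
#' @export
render_bland_altman <- function(table, fit, path, width = 7, height = 5) {
  p <- plot_bland_altman(table, fit)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  } else {
    rlang::abort("path must end in .svg or .png", class = "hragree_render_error")
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
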