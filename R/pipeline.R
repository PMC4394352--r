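# Orchestration: one call runs simulate (optional) -> quantify ->
# kinetics -> ratio / dose-response / abundance as configured, writes a
# result bundle (JSON + CSV + log) to a run directory and never touches
# its inputs.

#' Run the full analysis pipeline from a configuration
#'
#' The configuration is a YAML file or an equivalent named list. Blocks
#' (all optional except one data source for each requested stage):
#'
#' * `simulate`: arguments for [sim_config()]; simulated tables are
#'   written under `<out_dir>/inputs/` and then consumed like user data.
#' * `lanes`: path to a lane CSV ([lane_schema()]) if not simulating.
#' * `quantify`: `min_total_intensity`.
#' * `kinetics`: `time_point` (minutes, default 5), `intercept`
#'   (`"origin"`/`"free"`).
#' * `ratio`: `numerator` and `denominator` condition labels; the
#'   fold-change of their velocity-vs-substrate slopes is reported.
#' * `dose_response`: `table` (CSV path with `dose_uM`, `velocity`) or
#'   `simulate: true`; optional `exclude_above`.
#' * `abundance`: `standards`/`lysate` CSV paths or `simulate: true`;
#'   optional `saturation_tol`.
#'
#' An annotated example ships at
#' `system.file("extdata", "example_config.yaml", package = "holophos")`.
#'
#' @param config Path to a YAML file, or a named list.
#' @param seed Optional integer overriding the config seed for all
#'   simulated inputs.
#' @param out_dir Output directory (created if needed; default a fresh
#'   directory under `tempdir()`). Inputs are never modified; all
#'   outputs go here.
#' @return Invisibly, the result bundle: a list with `manifest`,
#'   `quantified`, `decay_rates`, `velocities`, `velocity_slopes`, and
#'   any of `ratio`, `dose_response`, `abundance` that were configured.
#'   `results.json` and per-stage CSVs are written to `out_dir`.
#' @export
run_pipeline <- function(config, seed = NULL,
                         out_dir = tempfile("holophos_run_")) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NA_character_
  }
  if (!is.list(config)) {
    abort("`config` must be a YAML path or a named list",
          class = "holophos_input_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)),
        file = log_path, append = TRUE)
  }
  flags <- character()
  note_flag <- function(stage, msg) {
    flags <<- c(flags, sprintf("%s: %s", stage, msg))
    log_line("WARNING %s: %s", stage, msg)
  }
  with_flags <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      note_flag(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  results <- list()
  log_line("holophos %s pipeline start", packageVersion("holophos"))

  sim_cfg <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    sim_cfg <- do.call(sim_config, sim_args)
    log_line("simulate: seed %d", sim_cfg$seed)
  }

  # ---- lanes -> quantify -> kinetics -------------------------------
  lanes <- NULL
  if (!is.null(sim_cfg)) {
    lanes <- simulate_timecourse(sim_cfg)
    readr::write_csv(lanes, file.path(out_dir, "inputs", "lanes.csv"))
  } else if (!is.null(config$lanes)) {
    lanes <- read_lane_table(config$lanes)
    log_line("lanes: read %d rows from %s", nrow(lanes), config$lanes)
  }

  if (!is.null(lanes)) {
    quantified <- with_flags("quantify", quantify_lanes(
      lanes,
      min_total_intensity = config$quantify$min_total_intensity %||% 0
    ))
    readr::write_csv(quantified, file.path(out_dir, "quantified.csv"))
    results$quantified <- quantified

    kin <- config$kinetics %||% list()
    decay <- with_flags("kinetics", fit_decay_rates(
      quantified, intercept = kin$intercept %||% "origin"
    ))
    readr::write_csv(decay, file.path(out_dir, "decay_rates.csv"))
    results$decay_rates <- decay

    vel <- with_flags("kinetics", compute_initial_velocities(
      quantified, time_point = kin$time_point %||% 5
    ))
    readr::write_csv(vel, file.path(out_dir, "velocities.csv"))
    results$velocities <- vel

    slopes <- vel |>
      dplyr::group_by(.data$condition_label) |>
      dplyr::group_modify(function(d, g) {
        tidy(velocity_vs_substrate(d, label = g$condition_label))
      }) |>
      dplyr::ungroup()
    readr::write_csv(slopes, file.path(out_dir, "velocity_slopes.csv"))
    results$velocity_slopes <- slopes
    log_line("kinetics: %d decay fits, %d velocity slopes",
             nrow(decay), nrow(slopes))

    if (!is.null(config$ratio)) {
      pick <- function(lab, what) {
        row <- slopes[slopes$condition_label == lab, ]
        if (nrow(row) != 1) {
          abort(sprintf("ratio %s condition '%s' not found uniquely",
                        what, lab),
                class = "holophos_input_error")
        }
        list(slope = row$estimate, stderr = row$std.error, dof = row$dof)
      }
      rat <- slope_ratio(pick(config$ratio$numerator, "numerator"),
                         pick(config$ratio$denominator, "denominator"),
                         level = config$ratio$level %||% 0.95)
      results$ratio <- rat
      log_line("ratio: %s / %s = %.4g", config$ratio$numerator,
               config$ratio$denominator, rat$ratio)
    }
  }

  # ---- dose-response -----------------------------------------------
  if (!is.null(config$dose_response)) {
    dr_cfg <- config$dose_response
    dr_tbl <- if (isTRUE(dr_cfg$simulate)) {
      if (is.null(sim_cfg)) {
        abort("dose_response simulate: true requires a simulate block",
              class = "holophos_input_error")
      }
      tbl <- simulate_dose_response(sim_cfg)
      readr::write_csv(tbl, file.path(out_dir, "inputs",
                                      "dose_response.csv"))
      tbl
    } else {
      tbl <- readr::read_csv(dr_cfg$table, show_col_types = FALSE,
                             progress = FALSE)
      check_columns(tbl, c("dose_uM", "velocity"),
                    sprintf("dose table '%s'", dr_cfg$table))
      tbl
    }
    fit <- with_flags("dose_response", fit_activation(
      dr_tbl, exclude_above = dr_cfg$exclude_above
    ))
    results$dose_response <- fit
    readr::write_csv(glance(fit), file.path(out_dir, "dose_response.csv"))
    log_line("dose_response: EC50 = %s uM",
             ifelse(is.na(fit$ec50), "undefined", format(fit$ec50)))
  }

  # ---- abundance ---------------------------------------------------
  if (!is.null(config$abundance)) {
    ab_cfg <- config$abundance
    model <- cell_volume_model()
    if (isTRUE(ab_cfg$simulate)) {
      if (is.null(sim_cfg)) {
        abort("abundance simulate: true requires a simulate block",
              class = "holophos_input_error")
      }
      blot <- simulate_blot(sim_cfg, model = model)
      readr::write_csv(blot$standards,
                       file.path(out_dir, "inputs", "standards.csv"))
      readr::write_csv(blot$lysate,
                       file.path(out_dir, "inputs", "lysate.csv"))
      standards <- blot$standards
      lysate <- blot$lysate
    } else {
      standards <- readr::read_csv(ab_cfg$standards,
                                   show_col_types = FALSE,
                                   progress = FALSE)
      check_columns(standards, c("mass_pmol", "signal"),
                    sprintf("standards table '%s'", ab_cfg$standards))
      lysate <- readr::read_csv(ab_cfg$lysate, show_col_types = FALSE,
                                progress = FALSE)
      check_columns(lysate, c("sample_id", "signal"),
                    sprintf("lysate table '%s'", ab_cfg$lysate))
    }
    curve <- with_flags("abundance", fit_calibration(
      standards, saturation_tol = ab_cfg$saturation_tol %||% 0.1
    ))
    conc <- with_flags("abundance",
                       estimate_abundance(lysate, curve, model))
    results$calibration <- curve
    results$abundance <- conc
    readr::write_csv(conc, file.path(out_dir, "abundance.csv"))
    log_line("abundance: %d sample(s), mean %.4g uM",
             nrow(conc), mean(conc$concentration_uM))
  }

  manifest <- list(
    package_version = as.character(packageVersion("holophos")),
    config_path = config_path,
    seed = if (!is.null(sim_cfg)) sim_cfg$seed else seed,
    out_dir = out_dir,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = names(results),
    flags = flags
  )
  results$manifest <- manifest

  json <- purrr::map(results, function(x) {
    if (inherits(x, c("ratio_estimate", "dose_response_fit",
                      "calibration_curve"))) {
      as.list(glance_or_tidy(x))
    } else if (is.data.frame(x)) {
      x
    } else {
      x
    }
  })
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_line("pipeline done: %s", paste(manifest$stages, collapse = ", "))
  invisible(results)
}

glance_or_tidy <- function(x) {
  if (inherits(x, "ratio_estimate")) tidy(x) else glance(x)
}
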