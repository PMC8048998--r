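#' Validate pipeline input tables
#'
#' Schema and units checks for the input CSV files: nest annotations,
#' detections, crèche dates, precipitation scores, krill catch and tourism
#' visits. Problems are reported per file as errors (schema violations)
#' or warnings (values the pipeline will coerce, e.g. counts above the
#' clutch cap).
#'
#' @param paths Named list of file paths; recognised names:
#'   `annotations`, `detections`, `site_years` (site/year metadata with
#'   crèche and first-chick dates), `precip`, `krill_catch`, `tourism`.
#'   Missing entries are skipped.
#' @returns A tibble with columns `file`, `level` (`"error"`/`"warning"`),
#'   `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(file, level, message) {
    out[[length(out) + 1]] <<- tibble::tibble(file = file, level = level,
                                              message = message)
  }
  read_or_note <- function(name) {
    p <- paths[[name]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) { note(name, "error", "file not found"); return(NULL) }
    tryCatch(readr::read_csv(p, show_col_types = FALSE, progress = FALSE),
             error = function(e) { note(name, "error", conditionMessage(e)); NULL })
  }
  need_cols <- function(name, df, cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      note(name, "error", paste("missing columns:", paste(missing, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }

  ann <- read_or_note("annotations")
  if (!is.null(ann) && need_cols("annotations", ann,
      c("site_id", "year_id", "nest_id", "x_px", "y_px", "frame_w", "frame_h"))) {
    oob <- ann$x_px < 0 | ann$x_px > ann$frame_w |
      ann$y_px < 0 | ann$y_px > ann$frame_h
    if (any(oob)) note("annotations", "error",
                       paste(sum(oob), "nest seed(s) outside the frame"))
    dup <- duplicated(ann[, c("site_id", "year_id", "x_px", "y_px")])
    if (any(dup)) note("annotations", "error", "duplicate nest seeds")
  }

  det <- read_or_note("detections")
  if (!is.null(det)) need_cols("detections", det,
                               c("site_id", "year_id", "timestamp", "x_px", "y_px"))

  sy <- read_or_note("site_years")
  if (!is.null(sy) && need_cols("site_years", sy,
      c("site_id", "year_id", "creche_date", "first_chick_date"))) {
    bad <- is.na(as.Date(sy$creche_date))
    if (any(bad)) note("site_years", "error",
                       paste("missing creche_date for",
                             paste(paste(sy$site_id[bad], sy$year_id[bad],
                                         sep = "/"), collapse = ", ")))
  }

  series <- read_or_note("series")
  if (!is.null(series) && need_cols("series", series,
      c("site_id", "year_id", "nest_id", "t", "count"))) {
    over <- !is.na(series$count) & series$count > 2
    if (any(over)) note("series", "warning",
                        paste(sum(over), "count(s) above the 2-chick clutch",
                              "cap; they will be capped"))
  }

  pr <- read_or_note("precip")
  if (!is.null(pr) && need_cols("precip", pr,
      c("site_id", "year_id", "date", "kind", "magnitude"))) {
    if (any(!pr$magnitude %in% 1:3))
      note("precip", "error", "magnitude outside {1, 2, 3}")
    if (any(!pr$kind %in% c("rain", "snow")))
      note("precip", "error", "kind must be 'rain' or 'snow'")
  }

  kr <- read_or_note("krill_catch")
  if (!is.null(kr) && need_cols("krill_catch", kr,
      c("ssmu_id", "year", "month", "tonnes"))) {
    if (any(kr$tonnes < 0)) note("krill_catch", "error", "negative tonnes")
    if (any(kr$tonnes == 0)) note("krill_catch", "warning",
                                  "zero catches present; log transform will use an offset")
  }

  tv <- read_or_note("tourism")
  if (!is.null(tv)) need_cols("tourism", tv,
                              c("site_id", "year_id", "date", "visitors"))

  if (length(out) == 0) {
    tibble::tibble(file = character(), level = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Run the full analysis pipeline on a simulated or file-based dataset
#'
#' Executes the stages in order — observation series, survival model fit,
#' derived trajectories and breeding success, phase mortality with the
#' Friedman test, and driver regressions — and writes all outputs plus a
#' manifest (config echo, seed, package version, convergence report, file
#' checksums) to `out_dir`. With `config$simulate` set, inputs come from
#' the synthetic-data generator; otherwise file paths must be supplied.
#'
#' @param config A named list (or YAML file path read with
#'   [read_pipeline_config()]) with entries `seed`, `out_dir`, `mcmc`
#'   (passed to [mcmc_config()]), `priors` (passed to
#'   [survival_priors()]), `phase_boundaries`, and either `simulate`
#'   (passed to [sim_config()]) or `inputs` (named file paths as in
#'   [validate_inputs()]).
#' @returns Invisibly, a list with the fit, derived tables and the
#'   manifest. Unknown config keys are an error.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  known <- c("seed", "out_dir", "mcmc", "priors", "phase_boundaries",
             "simulate", "inputs", "drivers")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  boundaries <- config$phase_boundaries %||% c(30, 45, 60)
  mcmc <- do.call(mcmc_config, modifyList(list(rng_seed = seed),
                                          config$mcmc %||% list()))
  priors <- do.call(survival_priors, config$priors %||% list())

  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    data <- stage("simulate", {
      cfg <- do.call(sim_config, modifyList(list(rng_seed = seed),
                                            config$simulate))
      simulate_dataset(cfg)
    })
    truth <- data$truth
  } else {
    inputs <- config$inputs %||% stop("config needs either $simulate or $inputs")
    rep <- validate_inputs(inputs)
    if (any(rep$level == "error"))
      stop("input validation failed:\n",
           paste(rep$file, rep$message, sep = ": ", collapse = "\n"))
    data <- stage("series", {
      series <- readr::read_csv(inputs$series, show_col_types = FALSE,
                                progress = FALSE)
      series$count[!is.na(series$count) & series$count > 2] <- 2L
      series
    })
  }

  fit <- stage("fit", fit_survival_model(data, priors = priors, mcmc = mcmc))
  bs <- breeding_success(fit)
  phases <- stage("phases", phase_mortality_fit(fit, boundaries))
  fried <- if (nrow(phases) >= 2) {
    friedman_rank_test(as.matrix(phases[, c("egg_rate", "young_rate",
                                            "old_rate")]))
  } else NULL

  files <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, na = "")
    files <<- c(files, p)
    p
  }
  wr(tidy(fit), "posterior_summary.csv")
  wr(posterior_draws(fit), "posterior_draws.csv")
  wr(bs, "breeding_success.csv")
  wr(phases, "phase_mortality.csv")
  traj <- purrr::map_dfr(seq_len(nrow(fit$site_years)), function(j) {
    tr <- total_chicks(fit, fit$site_years$site_id[j], fit$site_years$year_id[j])
    tr$site_id <- fit$site_years$site_id[j]
    tr$year_id <- fit$site_years$year_id[j]
    tr
  })
  wr(traj, "z_trajectories.csv")
  if (!is.null(truth)) wr(truth, "simulation_truth.csv")

  driver_fits <- NULL
  if (!is.null(config$drivers) && isTRUE(config$drivers$simulate)) {
    drv <- stage("drivers", {
      tab <- simulate_drivers(rng_seed = seed + 1000L)
      fitd <- fit_driver_regression(tab |> dplyr::rename(precip_events = "x"),
                                    "precip_events", rng_seed = seed + 2000L)
      list(table = tab, fit = fitd)
    })
    wr(drv$table, "driver_table.csv")
    wr(tidy(drv$fit), "driver_regression.csv")
    driver_fits <- drv$fit
  }

  g <- glance(fit)
  manifest <- list(
    package_version = as.character(utils::packageVersion("camcr")),
    seed = seed,
    mcmc = unclass(mcmc),
    priors = unclass(priors),
    phase_boundaries = boundaries,
    convergence = list(max_rhat = g$max_rhat,
                       min_ess_per_chain = g$min_ess_per_chain,
                       converged = g$converged),
    friedman = if (!is.null(fried)) unclass(tidy(fried)) else NULL,
    outputs = lapply(files, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(fit = fit, breeding_success = bs, phases = phases,
                 friedman = fried, driver_fit = driver_fits,
                 manifest = manifest, out_dir = out_dir))
}

#' @rdname run_pipeline
#' @param path YAML config file path.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
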