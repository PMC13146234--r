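#' Build and validate a pipeline configuration
#'
#' All analysis thresholds in one place: business hours, episode gap,
#' dwell screen, RSSI bands, exploratory-rule thresholds, validation
#' window, sensitivity grid, random-forest spec, the simulation scenario
#' and the master seed. Settings can be loaded from a YAML file and/or
#' overridden programmatically; every field has the study default.
#'
#' @param path optional YAML file; keys mirror the argument names below
#'   (scenario fields go under a \code{scenario:} mapping).
#' @param overrides optional named list applied after the file.
#' @return a validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    business_hours = c(10, 22),
    gap_threshold_s = 600,
    max_dwell_min = 6,
    smoker_band = c(-75, -46),
    passerby_band = c(-88, -76),
    explore_rssi_threshold = -80,
    explore_dwell_threshold = 10,
    validation_window = c("15:00:00", "15:30:00"),
    dwell_factors = c(0.8, 0.9, 1, 1.1, 1.2),
    rssi_factors = c(0.8, 0.9, 1, 1.1, 1.2),
    rf = list(n_trees = 10, max_depth = 5, min_node_size = 1,
              cv_folds = 5, test_fraction = 0.4),
    scenario = list()
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(from_file, overrides)) {
    for (nm in names(src)) {
      if (nm %in% c("rf", "scenario")) {
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(src[[nm]]))
      } else {
        cfg[[nm]] <- src[[nm]]
      }
    }
  }
  validate_bands(cfg$smoker_band, cfg$passerby_band)
  if (length(cfg$validation_window) != 2)
    abort_field("validation_window", "must be c(start, end) clock times")
  if (cfg$max_dwell_min <= 0) abort_field("max_dwell_min", "must be > 0")
  if (cfg$gap_threshold_s <= 0) abort_field("gap_threshold_s", "must be > 0")
  cfg$scenario_config <- do.call(scenario_config, cfg$scenario)
  cfg$rf_spec <- do.call(rf_spec, c(cfg$rf, list(seed = cfg$seed)))
  structure(cfg, class = "pipeline_config")
}

# validation-window POSIXct bounds on the scenario day
validation_window_bounds <- function(config) {
  sc <- config$scenario_config
  as.POSIXct(paste(sc$date, config$validation_window), tz = sc$tz)
}

#' Ground-truth manual counts for a window
#'
#' Emulates the trained observer's tally: persons of each class who
#' enter the assessment zone during the window (entry time in
#' \code{[start, end)}, closest approach within the radius) are counted,
#' regardless of whether they carried a device. Entry-based membership
#' mirrors the device-side convention (an episode is in-window when it
#' starts inside the window), so both sides of the capture ratio count
#' the same flow.
#'
#' @param truth ground-truth tibble from [generate_scenario()].
#' @param window POSIXct \code{c(start, end)}.
#' @param radius_m assessment radius in metres.
#' @return named vector \code{c(smoker = , passerby = )}.
#' @export
manual_counts_from_truth <- function(truth, window, radius_m = 25) {
  inw <- truth$entry >= window[1] & truth$entry < window[2] &
    truth$min_distance_m <= radius_m
  c(smoker = sum(inw & truth$class == "smoker"),
    passerby = sum(inw & truth$class == "passerby"))
}

log_stage <- function(...) message("[shscount] ", ...)

#' Run the full exposure-opportunity pipeline
#'
#' Simulates a day (or ingests a supplied log), applies the
#' preprocessing funnel, classifies eligible episodes, calibrates
#' against the validation window, scales to day totals and hourly
#' profiles, runs the threshold sensitivity grid and, when ground-truth
#' labels are available, the exploratory random-forest analysis. Stage
#' counts are logged to standard error; machine-readable outputs are
#' written under \code{out_dir} when given (funnel JSON, classified
#' episodes CSV, day-estimate JSON, sensitivity CSV, RF report JSON).
#' Re-running with the same configuration and seed reproduces every
#' output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param log_path optional path to an existing probe log (CSV); when
#'   \code{NULL} the scenario simulator supplies the data.
#' @param truth optional ground-truth tibble matching \code{log_path}.
#' @return list: \code{funnel}, \code{classified}, \code{ratios},
#'   \code{day_estimate}, \code{hourly}, \code{sensitivity},
#'   \code{rf_report} (NULL without labels), \code{validation},
#'   \code{truth}, \code{ingest_report}.
#' @export
run_pipeline <- function(config, out_dir = NULL, log_path = NULL,
                         truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario_config

  if (is.null(log_path)) {
    log_stage("simulating scenario (seed ", config$seed, ")")
    sim <- generate_scenario(sc, config$seed)
    records <- sim$log
    truth <- sim$truth
    ingest_report <- NULL
  } else {
    log_stage("ingesting ", log_path)
    ing <- read_probe_log(log_path, "csv", tz = sc$tz)
    records <- ing$records
    ingest_report <- ing$report
  }
  log_stage("detections: ", nrow(records))

  pp <- preprocess(records, config$business_hours, config$gap_threshold_s,
                   config$max_dwell_min)
  log_stage("funnel: ",
            paste(pp$funnel$stage, pp$funnel$count, collapse = " | "))

  classified <- classify_episodes(pp$eligible, config$smoker_band,
                                  config$passerby_band,
                                  config$explore_rssi_threshold,
                                  config$explore_dwell_threshold)
  log_stage("classified: ",
            sum(classified$primary_label == "smoker"), " smoker / ",
            sum(classified$primary_label == "passerby"), " passerby / ",
            sum(classified$primary_label == "unclassified"), " unclassified")

  window <- validation_window_bounds(config)
  if (is.null(truth))
    stop("calibration requires ground truth or manual counts", call. = FALSE)
  manual <- manual_counts_from_truth(truth, window, sc$assessment_radius)
  wdev <- window_device_counts(classified, window[1], window[2])
  validation <- validation_counts(manual[["smoker"]], manual[["passerby"]],
                                  wdev[["smoker"]], wdev[["passerby"]],
                                  window)
  ratios <- compute_ratios(validation)
  log_stage("multipliers: smoker ", ratios$multiplier[["smoker"]],
            ", passerby ", ratios$multiplier[["passerby"]])

  devices <- c(smoker = sum(classified$primary_label == "smoker"),
               passerby = sum(classified$primary_label == "passerby"))
  day_estimate <- estimate_day_totals(devices, ratios)
  hourly <- hourly_profile(classified, ratios)
  log_stage("day totals: ",
            paste(day_estimate$class, day_estimate$persons, collapse = ", "))

  sens <- sensitivity_analysis(pp$episodes, manual, window,
                               config$max_dwell_min, config$smoker_band,
                               config$passerby_band, config$dwell_factors,
                               config$rssi_factors)

  rf_report <- NULL
  ep_labels <- episode_truth_labels(classified, truth)
  if (!is.null(ep_labels)) {
    keep <- !is.na(ep_labels)
    labelled <- classified[keep, , drop = FALSE]
    ep_labels <- droplevels(ep_labels[keep])
    if (nlevels(ep_labels) == 2 && min(table(ep_labels)) >= 2) {
      log_stage("fitting exploratory random forest on ",
                length(ep_labels), " labelled stays")
      rf_report <- train_and_evaluate(summarize_episode(labelled),
                                      factor(ep_labels,
                                             levels = c("nonsmoker", "smoker")),
                                      config$rf_spec)
    }
  }

  result <- list(funnel = pp$funnel, classified = classified,
                 ratios = ratios, day_estimate = day_estimate,
                 hourly = hourly, sensitivity = sens,
                 rf_report = rf_report, validation = validation,
                 truth = truth, ingest_report = ingest_report)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# smoker/nonsmoker truth labels for classified episodes, by device id;
# NULL when no episode device appears in the truth table
episode_truth_labels <- function(episodes, truth) {
  if (is.null(truth) || nrow(truth) == 0) return(NULL)
  m <- match(episodes$device_id, truth$device_id)
  if (all(is.na(m))) return(NULL)
  cls <- truth$class[m]
  out <- ifelse(is.na(cls), NA_character_,
                ifelse(cls == "smoker", "smoker", "nonsmoker"))
  factor(out, levels = c("nonsmoker", "smoker"))
}

#' Write pipeline outputs to disk
#'
#' @param result a [run_pipeline()] result list.
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jw <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  jw(list(funnel = result$funnel), "funnel.json")

  cl <- result$classified
  cl$start <- format_probe_time(cl$start)
  cl$end <- format_probe_time(cl$end)
  utils::write.csv(cl, file.path(out_dir, "classified_episodes.csv"),
                   row.names = FALSE)

  jw(list(
    validation = list(
      manual = as.list(result$validation$manual),
      devices = as.list(result$validation$devices)),
    capture_pct = as.list(result$ratios$capture_pct),
    multiplier = as.list(result$ratios$multiplier),
    day_estimate = result$day_estimate
  ), "day_estimate.json")

  utils::write.csv(result$sensitivity,
                   file.path(out_dir, "sensitivity.csv"), row.names = FALSE)

  if (!is.null(result$rf_report)) {
    r <- result$rf_report
    jw(list(confusion = as.list(r$confusion), accuracy = r$accuracy,
            sensitivity = r$sensitivity, specificity = r$specificity,
            weighted = as.list(r$weighted), auc = r$auc,
            cv_accuracy = r$cv_accuracy, n_test = r$n_test),
       "rf_report.json")
  }
  invisible(out_dir)
}
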