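#' Validation-window counts
#'
#' Pairs the manual observation counts (persons, from a trained observer
#' tallying inside the assessment radius) with the concurrent
#' sensor-classified device counts for the same window.
#'
#' @param manual_smokers,manual_passersby observed persons per class.
#' @param device_smokers,device_passersby classified devices per class
#'   whose episode starts inside the window.
#' @param window optional \code{c(start, end)} POSIXct bounds, carried
#'   along for reporting.
#' @return a \code{validation_counts} list.
#' @export
validation_counts <- function(manual_smokers, manual_passersby,
                              device_smokers, device_passersby,
                              window = NULL) {
  counts <- c(manual_smokers, manual_passersby,
              device_smokers, device_passersby)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(
    list(manual = c(smoker = manual_smokers, passerby = manual_passersby),
         devices = c(smoker = device_smokers, passerby = device_passersby),
         window = window),
    class = "validation_counts"
  )
}

#' Class-specific calibration ratios
#'
#' For each behavioral class the capture ratio is classified devices
#' divided by observed persons, and the device-to-person multiplier is
#' its inverse, persons per device, rounded half-up to one decimal.
#' The rounded multiplier — not the exact ratio — is what scales device
#' counts in [estimate_day_totals()]; this convention is what makes the
#' day-total arithmetic self-consistent with integer eligible-episode
#' counts.
#'
#' @param v a [validation_counts()] object.
#' @return a \code{calibration_ratios} list with per-class
#'   \code{capture_ratio} (fraction), \code{capture_pct} (one decimal)
#'   and \code{multiplier} (persons/device, one decimal).
#' @export
#' @examples
#' v <- validation_counts(14, 207, 7, 28)
#' compute_ratios(v)
compute_ratios <- function(v) {
  for (cls in c("smoker", "passerby")) {
    if (v$manual[[cls]] <= 0)
      stop("calibration undefined for class '", cls,
           "': zero manual count", call. = FALSE)
    if (v$devices[[cls]] <= 0)
      stop("calibration undefined for class '", cls,
           "': zero classified device count", call. = FALSE)
  }
  capture <- v$devices / v$manual
  multiplier <- round_half_up(v$manual / v$devices, 1)
  structure(
    list(capture_ratio = capture,
         capture_pct = round_half_up(100 * capture, 1),
         multiplier = multiplier),
    class = "calibration_ratios"
  )
}

#' Scale classified device counts to day-level person totals
#'
#' Persons per class = round(devices x multiplier) to the nearest
#' integer (half up), using the one-decimal multiplier from
#' [compute_ratios()].
#'
#' @param devices named numeric \code{c(smoker = ..., passerby = ...)}
#'   of classified devices over the analysis window (business hours).
#' @param ratios a [compute_ratios()] result.
#' @return tibble with \code{class}, \code{devices}, \code{multiplier},
#'   \code{persons}.
#' @export
#' @examples
#' r <- compute_ratios(validation_counts(14, 207, 7, 28))
#' estimate_day_totals(c(smoker = 131, passerby = 528), r)
estimate_day_totals <- function(devices, ratios) {
  if (!inherits(ratios, "calibration_ratios"))
    stop("`ratios` must come from compute_ratios()", call. = FALSE)
  cls <- c("smoker", "passerby")
  if (!all(cls %in% names(devices)))
    stop("`devices` must be named c(smoker = , passerby = )", call. = FALSE)
  dev <- as.numeric(devices[cls])
  mult <- as.numeric(ratios$multiplier[cls])
  tibble::tibble(
    class = cls,
    devices = dev,
    multiplier = mult,
    persons = round_half_up(dev * mult, 0)
  )
}

#' Hourly person-count profile
#'
#' Assigns each classified episode to the hour of its start time and
#' scales hourly device counts by the class multiplier. Hourly values
#' are kept unrounded internally and rescaled proportionally so that
#' each class's hourly profile sums exactly to its rounded day total.
#'
#' @param classified episode tibble with a \code{primary_label} column.
#' @param ratios a [compute_ratios()] result.
#' @return tibble: \code{class}, \code{hour} (0-23), \code{devices},
#'   \code{persons} (proportional, sums to the day total per class).
#' @export
hourly_profile <- function(classified, ratios) {
  cls <- c("smoker", "passerby")
  out <- list()
  for (k in cls) {
    ep <- classified[classified$primary_label == k, , drop = FALSE]
    hrs <- lubridate::hour(ep$start)
    dev_h <- as.numeric(table(factor(hrs, levels = 0:23)))
    raw <- dev_h * ratios$multiplier[[k]]
    total <- round_half_up(sum(dev_h) * ratios$multiplier[[k]], 0)
    persons <- if (sum(raw) > 0) raw * total / sum(raw) else raw
    out[[k]] <- tibble::tibble(class = k, hour = 0:23,
                               devices = dev_h, persons = persons)
  }
  dplyr::bind_rows(out)
}

# count classified devices per class with episode start inside [start, end)
window_device_counts <- function(classified, start, end) {
  inw <- classified$start >= start & classified$start < end
  c(
    smoker = sum(inw & classified$primary_label == "smoker"),
    passerby = sum(inw & classified$primary_label == "passerby")
  )
}

#' Threshold sensitivity analysis
#'
#' Re-runs the classification-and-calibration chain over a grid of
#' multiplicative perturbations of the dwell screen and the RSSI band
#' edges (default -20% to +20%). Each grid point re-screens the
#' pre-screen episodes, re-classifies, re-derives the calibration ratios
#' from the validation window (manual counts held fixed) and re-scales
#' to day totals. Grid points whose perturbed bands would overlap, or
#' whose validation window yields a zero device count, are flagged
#' invalid with a reason rather than silently skipped.
#'
#' @param episodes pre-screen episode tibble (from
#'   \code{preprocess()$episodes}).
#' @param manual named \code{c(smoker = , passerby = )} manual person
#'   counts for the validation window.
#' @param window POSIXct \code{c(start, end)} validation-window bounds.
#' @param max_dwell_min baseline dwell screen (minutes).
#' @param smoker_band,passerby_band baseline RSSI bands (dBm).
#' @param dwell_factors,rssi_factors multiplicative perturbations
#'   applied to the dwell threshold and to every band edge.
#' @return tibble: one row per grid point with the perturbation factors,
#'   validity flag/reason, per-class device counts, multipliers, day
#'   totals and percent change versus the unperturbed baseline.
#' @export
sensitivity_analysis <- function(episodes, manual, window,
                                 max_dwell_min = 6,
                                 smoker_band = c(-75, -46),
                                 passerby_band = c(-88, -76),
                                 dwell_factors = c(0.8, 0.9, 1, 1.1, 1.2),
                                 rssi_factors = c(0.8, 0.9, 1, 1.1, 1.2)) {
  run_point <- function(fd, fr) {
    dwell <- max_dwell_min * fd
    sb <- smoker_band * fr
    pb <- passerby_band * fr
    ok_bands <- tryCatch({ validate_bands(sb, pb); TRUE },
                         error = function(e) FALSE)
    row <- tibble::tibble(
      dwell_factor = fd, rssi_factor = fr, valid = FALSE,
      reason = NA_character_,
      smoker_devices = NA_real_, passerby_devices = NA_real_,
      smoker_multiplier = NA_real_, passerby_multiplier = NA_real_,
      smoker_total = NA_real_, passerby_total = NA_real_
    )
    if (!ok_bands) {
      row$reason <- "band_overlap"
      return(row)
    }
    elig <- apply_dwell_screen(episodes, dwell)
    cl <- classify_episodes(elig, sb, pb)
    wdev <- window_device_counts(cl, window[1], window[2])
    if (any(wdev == 0)) {
      row$reason <- "zero_window_devices"
      return(row)
    }
    ratios <- compute_ratios(validation_counts(
      manual[["smoker"]], manual[["passerby"]],
      wdev[["smoker"]], wdev[["passerby"]], window))
    dev <- c(smoker = sum(cl$primary_label == "smoker"),
             passerby = sum(cl$primary_label == "passerby"))
    est <- estimate_day_totals(dev, ratios)
    row$valid <- TRUE
    row$smoker_devices <- dev[["smoker"]]
    row$passerby_devices <- dev[["passerby"]]
    row$smoker_multiplier <- ratios$multiplier[["smoker"]]
    row$passerby_multiplier <- ratios$multiplier[["passerby"]]
    row$smoker_total <- est$persons[est$class == "smoker"]
    row$passerby_total <- est$persons[est$class == "passerby"]
    row
  }
  grid <- expand.grid(dwell_factor = dwell_factors,
                      rssi_factor = rssi_factors)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    run_point(grid$dwell_factor[i], grid$rssi_factor[i]))
  tab <- dplyr::bind_rows(rows)
  base <- tab[tab$dwell_factor == 1 & tab$rssi_factor == 1, , drop = FALSE]
  if (nrow(base) == 1 && isTRUE(base$valid)) {
    tab$smoker_pct_change <-
      round_half_up(100 * (tab$smoker_total - base$smoker_total) /
                      base$smoker_total, 1)
    tab$passerby_pct_change <-
      round_half_up(100 * (tab$passerby_total - base$passerby_total) /
                      base$passerby_total, 1)
  } else {
    tab$smoker_pct_change <- NA_real_
    tab$passerby_pct_change <- NA_real_
  }
  tab
}
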