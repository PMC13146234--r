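#' Default hourly arrival rates for smokers
#'
#' Persons per hour by hour of day (0-23). The default emulates a
#' high-footfall event day at an outdoor smoking area: arrivals only
#' during business hours (10:00-22:00), with a bimodal shape peaking
#' around noon and 16:00 and a day total of about 260 smokers.
#'
#' @return numeric vector of length 24.
#' @export
default_smoker_rates <- function() {
  r <- numeric(24)
  r[11:22] <- c(12, 20, 34, 26, 22, 26, 34, 26, 20, 16, 14, 10) # hours 10..21
  r
}

#' Default hourly arrival rates for passersby
#'
#' Persons per hour by hour of day (0-23). The default emulates a
#' pedestrian corridor on an event day: a midday peak exceeding 500
#' persons per hour from late morning through mid-afternoon and a day
#' total of about 4000 passersby.
#'
#' @return numeric vector of length 24.
#' @export
default_passerby_rates <- function() {
  r <- numeric(24)
  r[11:22] <- c(240, 520, 600, 540, 520, 510, 505, 280, 150, 90, 60, 40)
  r
}

#' Default fixed-device roster
#'
#' Stationary infrastructure transmitters (access points, beacons) that
#' emit probe traffic around the clock. Their OUIs are distinct from the
#' phone-vendor pool used for simulated personal devices, so the
#' out-of-hours exclusion rule can be validated against ground truth.
#'
#' @return tibble with columns \code{oui}, \code{x}, \code{y},
#'   \code{inter_burst_mean_s}.
#' @export
default_fixed_devices <- function() {
  tibble::tibble(
    oui = c("0080C8", "00904C", "04A151"),
    x = c(5, -8, 2),
    y = c(5, 2, 20),
    inter_burst_mean_s = 60
  )
}

# vendor OUIs assigned to simulated personal devices
phone_oui_pool <- function() {
  c("A4C138", "F0D1A9", "3C2EFF", "D0C5F3", "8C8590", "60F445", "BC926B", "28E14C")
}

#' Build and validate a simulation scenario configuration
#'
#' Describes an outdoor smoking area adjacent to a pedestrian corridor,
#' monitored by a single passive Wi-Fi packet sensor at the coordinate
#' origin. Distances are metres, powers dBm, times local clock
#' (\code{tz}). The geometry defaults mirror the study site: the smoking
#' area fence about 3 m from the sensor, a corridor crossing laterally
#' some 13-17 m away, and a 25 m circular assessment zone.
#'
#' @param date simulated calendar day, \code{"YYYY-MM-DD"}.
#' @param tz Olson timezone of the site clock.
#' @param smoking_center x/y of the smoking-area centre (m from sensor).
#' @param dwell_zone_radius radius (m) within which smokers linger.
#' @param corridor_offset perpendicular distance (m) from the sensor to the
#'   corridor centreline.
#' @param corridor_width corridor width (m).
#' @param corridor_half_length half the monitored corridor length (m);
#'   passersby traverse the full \code{2 * corridor_half_length}.
#' @param walking_speed passerby walking speed (m/s).
#' @param assessment_radius radius (m) of the exposure assessment zone.
#' @param business_hours numeric \code{c(start, end)} local clock hours.
#' @param smoker_rates,passerby_rates length-24 vectors of arrivals
#'   (persons/hour) by hour of day.
#' @param smoker_stay_median_min median smoker stay (minutes) of the
#'   log-normal stay distribution.
#' @param smoker_stay_sdlog log-scale SD of smoker stays.
#' @param passerby_speed_sdlog log-scale SD of per-person walking speed
#'   (jitters traverse duration around corridor length / speed).
#' @param smoker_carriage,passerby_carriage probability that a person of
#'   each class carries a detectable personal device.
#' @param inter_burst_mean_s mean of the exponential inter-burst interval
#'   of the probe-emission process (seconds).
#' @param burst_size_range integer \code{c(min, max)} probes per burst
#'   (uniform).
#' @param path_loss list \code{p0} (dBm at reference distance),
#'   \code{d0} (reference distance, m), \code{exponent}, \code{shadow_sd}
#'   (dB) of the log-distance path-loss model.
#' @param rssi_floor weakest RSSI (dBm) the sensor logs.
#' @param fixed_devices roster tibble as in [default_fixed_devices()].
#' @param salt salt string for device-identifier hashing.
#' @return a validated \code{scenario_config} list.
#' @seealso [generate_scenario()]
#' @export
scenario_config <- function(date = "2023-10-28",
                            tz = "Asia/Tokyo",
                            smoking_center = c(3.15, 0),
                            dwell_zone_radius = 1.5,
                            corridor_offset = 15,
                            corridor_width = 4,
                            corridor_half_length = 15,
                            walking_speed = 1.2,
                            assessment_radius = 25,
                            business_hours = c(10, 22),
                            smoker_rates = default_smoker_rates(),
                            passerby_rates = default_passerby_rates(),
                            smoker_stay_median_min = 6,
                            smoker_stay_sdlog = 0.5,
                            passerby_speed_sdlog = 0.15,
                            smoker_carriage = 0.5,
                            passerby_carriage = 0.135,
                            inter_burst_mean_s = 30,
                            burst_size_range = c(1L, 4L),
                            path_loss = list(p0 = -40, d0 = 1,
                                             exponent = 3.5, shadow_sd = 4),
                            rssi_floor = -95,
                            fixed_devices = default_fixed_devices(),
                            salt = "shscount-demo") {
  cfg <- structure(
    list(
      date = date, tz = tz,
      smoking_center = smoking_center,
      dwell_zone_radius = dwell_zone_radius,
      corridor_offset = corridor_offset,
      corridor_width = corridor_width,
      corridor_half_length = corridor_half_length,
      walking_speed = walking_speed,
      assessment_radius = assessment_radius,
      business_hours = business_hours,
      smoker_rates = smoker_rates,
      passerby_rates = passerby_rates,
      smoker_stay_median_min = smoker_stay_median_min,
      smoker_stay_sdlog = smoker_stay_sdlog,
      passerby_speed_sdlog = passerby_speed_sdlog,
      smoker_carriage = smoker_carriage,
      passerby_carriage = passerby_carriage,
      inter_burst_mean_s = inter_burst_mean_s,
      burst_size_range = as.integer(burst_size_range),
      path_loss = path_loss,
      rssi_floor = rssi_floor,
      fixed_devices = fixed_devices,
      salt = salt
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
}

#' Validate a scenario configuration
#'
#' Checks rate, probability, geometry and path-loss invariants; errors
#' name the offending field.
#'
#' @param cfg a \code{scenario_config} list.
#' @return \code{cfg}, invisibly unchanged, if valid.
#' @export
validate_scenario_config <- function(cfg) {
  for (fld in c("smoker_rates", "passerby_rates")) {
    r <- cfg[[fld]]
    if (length(r) != 24 || any(!is.finite(r)))
      abort_field(fld, "must be a finite numeric vector of length 24")
    if (any(r < 0)) abort_field(fld, "rates must be >= 0")
  }
  for (fld in c("smoker_carriage", "passerby_carriage")) {
    p <- cfg[[fld]]
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
      abort_field(fld, "must be a probability in [0, 1]")
  }
  pl <- cfg$path_loss
  if (is.null(pl$d0) || pl$d0 <= 0) abort_field("path_loss$d0", "must be > 0")
  if (is.null(pl$shadow_sd) || pl$shadow_sd < 0)
    abort_field("path_loss$shadow_sd", "must be >= 0")
  if (cfg$assessment_radius <= 0) abort_field("assessment_radius", "must be > 0")
  if (cfg$dwell_zone_radius <= 0) abort_field("dwell_zone_radius", "must be > 0")
  if (cfg$walking_speed <= 0) abort_field("walking_speed", "must be > 0")
  bh <- cfg$business_hours
  if (length(bh) != 2 || bh[1] >= bh[2])
    abort_field("business_hours", "must be c(start, end) with start < end")
  if (cfg$inter_burst_mean_s <= 0)
    abort_field("inter_burst_mean_s", "must be > 0")
  br <- cfg$burst_size_range
  if (length(br) != 2 || br[1] < 1 || br[1] > br[2])
    abort_field("burst_size_range", "must be c(min, max) with 1 <= min <= max")
  fd <- cfg$fixed_devices
  if (!is.data.frame(fd) ||
      !all(c("oui", "x", "y", "inter_burst_mean_s") %in% names(fd)))
    abort_field("fixed_devices",
                "must have columns oui, x, y, inter_burst_mean_s")
  invisible(cfg)
}
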