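#' Per-episode signal features
#'
#' Dwell time (minutes), mean RSSI (dBm), RSSI standard deviation (dB,
#' sample SD) and detection count for each episode — the feature set
#' used by both the band rule and the exploratory classifier. Episodes
#' carry at least two detections by construction, so the sample SD is
#' always defined.
#'
#' @param episodes episode tibble from [build_episodes()].
#' @return tibble: \code{device_id}, \code{dwell_min}, \code{mean_rssi},
#'   \code{sd_rssi}, \code{n_detections}.
#' @export
summarize_episode <- function(episodes) {
  if (any(episodes$n_detections < 2))
    stop("episodes must have at least 2 detections", call. = FALSE)
  tibble::tibble(
    device_id = episodes$device_id,
    dwell_min = episodes$dwell_min,
    mean_rssi = episodes$mean_rssi,
    sd_rssi = episodes$sd_rssi,
    n_detections = episodes$n_detections
  )
}

#' Validate RSSI classification bands
#'
#' The smoker band must lie strictly above (closer to the sensor than)
#' the passerby band, with no overlap, for the rule-based classification
#' to be meaningful; a perturbation that makes the bands touch or
#' overlap is refused.
#'
#' @param smoker_band numeric \code{c(low, high)} dBm, inclusive.
#' @param passerby_band numeric \code{c(low, high)} dBm, inclusive.
#' @return \code{TRUE}, invisibly, if valid; otherwise an error.
#' @export
validate_bands <- function(smoker_band, passerby_band) {
  if (length(smoker_band) != 2 || smoker_band[1] > smoker_band[2])
    abort_field("smoker_band", "must be c(low, high) with low <= high")
  if (length(passerby_band) != 2 || passerby_band[1] > passerby_band[2])
    abort_field("passerby_band", "must be c(low, high) with low <= high")
  if (passerby_band[2] >= smoker_band[1])
    stop("RSSI bands overlap: passerby upper bound ",
         passerby_band[2], " dBm reaches into smoker band [",
         smoker_band[1], ", ", smoker_band[2], "]", call. = FALSE)
  invisible(TRUE)
}

#' Rule-based episode classification by RSSI band
#'
#' Episodes whose mean RSSI falls inside the smoker band (default -75 to
#' -46 dBm, inclusive) are labelled likely smokers; inside the passerby
#' band (default -88 to -76 dBm) likely passersby; anything stronger
#' than the smoker band or weaker than the passerby band is
#' \code{"unclassified"} and excluded from calibration and estimation.
#' RSSI is a proximity proxy: smokers linger near the smoking area close
#' to the sensor, passersby cross the corridor farther away.
#'
#' @param mean_rssi numeric vector of episode mean RSSI (dBm).
#' @param smoker_band,passerby_band inclusive \code{c(low, high)} dBm
#'   bands; must not overlap.
#' @return factor with levels \code{smoker}, \code{passerby},
#'   \code{unclassified}.
#' @export
#' @examples
#' classify_primary(c(-60, -80, -45, -89))
classify_primary <- function(mean_rssi,
                             smoker_band = c(-75, -46),
                             passerby_band = c(-88, -76)) {
  validate_bands(smoker_band, passerby_band)
  lab <- rep("unclassified", length(mean_rssi))
  lab[mean_rssi >= smoker_band[1] & mean_rssi <= smoker_band[2]] <- "smoker"
  lab[mean_rssi >= passerby_band[1] & mean_rssi <= passerby_band[2]] <- "passerby"
  factor(lab, levels = c("smoker", "passerby", "unclassified"))
}

#' Exploratory threshold rule
#'
#' Labels an episode a smoker stay when mean RSSI exceeds -80 dBm
#' \emph{and} dwell is under 10 minutes; otherwise nonsmoker. This is
#' the simple two-threshold rule examined alongside the random-forest
#' model, not the primary estimation rule.
#'
#' @param mean_rssi numeric vector, dBm.
#' @param dwell_min numeric vector, minutes.
#' @param rssi_threshold strict lower bound on mean RSSI (default -80).
#' @param dwell_threshold strict upper bound on dwell (default 10).
#' @return factor with levels \code{smoker}, \code{nonsmoker}.
#' @export
classify_exploratory <- function(mean_rssi, dwell_min,
                                 rssi_threshold = -80,
                                 dwell_threshold = 10) {
  smoker <- mean_rssi > rssi_threshold & dwell_min < dwell_threshold
  factor(ifelse(smoker, "smoker", "nonsmoker"),
         levels = c("smoker", "nonsmoker"))
}

#' Classify eligible episodes
#'
#' Adds the primary band-rule label and the exploratory threshold-rule
#' label to an episode table.
#'
#' @param episodes eligible episode tibble.
#' @inheritParams classify_primary
#' @inheritParams classify_exploratory
#' @return the episode tibble with \code{primary_label} and
#'   \code{exploratory_label} columns.
#' @export
classify_episodes <- function(episodes,
                              smoker_band = c(-75, -46),
                              passerby_band = c(-88, -76),
                              rssi_threshold = -80,
                              dwell_threshold = 10) {
  episodes$primary_label <-
    classify_primary(episodes$mean_rssi, smoker_band, passerby_band)
  episodes$exploratory_label <-
    classify_exploratory(episodes$mean_rssi, episodes$dwell_min,
                         rssi_threshold, dwell_threshold)
  episodes
}
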