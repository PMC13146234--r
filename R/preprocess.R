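#' Restrict detections to business hours
#'
#' Keeps records whose local clock time falls in the half-open window
#' \code{[start, end)}; the default window is 10:00-22:00. The boundary
#' convention means a record at exactly 10:00:00 is kept and one at
#' 22:00:00 is not.
#'
#' @param records canonical probe-record tibble.
#' @param window numeric \code{c(start, end)} local clock hours.
#' @return filtered records.
#' @export
filter_business_hours <- function(records, window = c(10, 22)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  h <- local_hour(records$timestamp)
  records[h >= window[1] & h < window[2], , drop = FALSE]
}

#' Identify fixed-infrastructure OUIs
#'
#' Vendor prefixes observed transmitting outside business hours are
#' taken to belong to stationary devices (access points, beacons) rather
#' than transient visitors: a human-carried phone is not expected on
#' site at 3 AM, while infrastructure transmits around the clock.
#' Exclusion is at OUI granularity, so a personal device sharing a
#' vendor prefix with a fixed device is excluded too (collateral
#' exclusion is a measurable property of the rule, not prevented).
#'
#' @param records canonical probe-record tibble spanning at least one
#'   out-of-hours period (otherwise the rule has no power and returns
#'   the empty set).
#' @param window business-hours window as in [filter_business_hours()].
#' @return character vector of OUIs to exclude.
#' @export
identify_fixed_ouis <- function(records, window = c(10, 22)) {
  if (nrow(records) == 0) return(character(0))
  h <- local_hour(records$timestamp)
  outside <- h < window[1] | h >= window[2]
  sort(unique(records$oui[outside]))
}

#' Drop all records bearing the given OUIs
#'
#' @param records canonical probe-record tibble.
#' @param ouis character vector, e.g. from [identify_fixed_ouis()].
#' @return filtered records.
#' @export
exclude_ouis <- function(records, ouis) {
  records[!(records$oui %in% ouis), , drop = FALSE]
}

#' Aggregate detections into presence episodes
#'
#' Per device identifier, consecutive detections separated by at most
#' \code{gap_threshold_s} seconds join one episode; a larger gap starts
#' a new one. Dwell is last minus first detection time within the
#' episode. Groups with a single detection have no defined dwell and are
#' discarded, so a device seen exactly once never yields an episode.
#'
#' @param records canonical probe-record tibble (time-sorted,
#'   post-filtering).
#' @param gap_threshold_s maximum intra-episode gap in seconds
#'   (default 600).
#' @return episode tibble: \code{device_id}, \code{oui}, \code{start},
#'   \code{end}, \code{dwell_min}, \code{n_detections},
#'   \code{mean_rssi}, \code{sd_rssi}.
#' @export
build_episodes <- function(records, gap_threshold_s = 600) {
  empty <- tibble::tibble(
    device_id = character(), oui = character(),
    start = records$timestamp[0], end = records$timestamp[0],
    dwell_min = numeric(), n_detections = integer(),
    mean_rssi = numeric(), sd_rssi = numeric()
  )
  if (nrow(records) == 0) return(empty)
  r <- records[order(records$device_id, records$timestamp), , drop = FALSE]
  tnum <- as.numeric(r$timestamp)
  new_dev <- c(TRUE, r$device_id[-1] != r$device_id[-nrow(r)])
  gap <- c(0, diff(tnum))
  new_ep <- new_dev | gap > gap_threshold_s
  ep_id <- cumsum(new_ep)
  ep <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(ep_id = ep_id, device_id = r$device_id, oui = r$oui,
                     timestamp = r$timestamp, rssi = r$rssi),
      ep_id
    ),
    device_id = device_id[1],
    oui = oui[1],
    start = min(timestamp),
    end = max(timestamp),
    n_detections = dplyr::n(),
    mean_rssi = mean(rssi),
    sd_rssi = stats::sd(rssi),
    .groups = "drop"
  )
  ep <- ep[ep$n_detections >= 2, , drop = FALSE]
  ep$dwell_min <- as.numeric(difftime(ep$end, ep$start, units = "mins"))
  ep <- ep[order(ep$start, ep$device_id), , drop = FALSE]
  tibble::as_tibble(ep[, c("device_id", "oui", "start", "end", "dwell_min",
                           "n_detections", "mean_rssi", "sd_rssi")])
}

#' Apply the dwell-time eligibility screen
#'
#' Retains episodes with dwell time at or below the threshold (inclusive
#' boundary: a 6.00-minute episode passes the default screen). The
#' screen limits overcounting from long-lingering devices and is the
#' knob the sensitivity analysis perturbs.
#'
#' @param episodes episode tibble from [build_episodes()].
#' @param max_dwell_min dwell ceiling in minutes (default 6).
#' @return eligible episodes.
#' @export
apply_dwell_screen <- function(episodes, max_dwell_min = 6) {
  episodes[episodes$dwell_min <= max_dwell_min, , drop = FALSE]
}

#' Summarize the preprocessing funnel
#'
#' Each stage count is expressed as a percentage of total detections
#' (the only denominator choice consistent across detection-level and
#' identifier-level stages), rounded half-up to one decimal. A zero
#' total defines all percentages as 0.
#'
#' @param total_detections all detections on the analysis day.
#' @param business_hours_detections detections inside business hours.
#' @param repeat_identifiers identifiers detected more than once.
#' @param dwell_identifiers identifiers with at least one computable
#'   dwell (an episode).
#' @param eligible_episodes episodes surviving the dwell screen.
#' @return tibble with columns \code{stage}, \code{count}, \code{pct}.
#' @export
#' @examples
#' compute_funnel(128313, 115950, 11068, 1817, 659)
compute_funnel <- function(total_detections, business_hours_detections,
                           repeat_identifiers, dwell_identifiers,
                           eligible_episodes) {
  counts <- c(
    total_detections = total_detections,
    business_hours_detections = business_hours_detections,
    repeat_identifiers = repeat_identifiers,
    dwell_identifiers = dwell_identifiers,
    eligible_episodes = eligible_episodes
  )
  pct <- if (total_detections > 0)
    round_half_up(100 * counts / total_detections, 1) else rep(0, 5)
  tibble::tibble(stage = names(counts), count = as.numeric(counts),
                 pct = as.numeric(pct))
}

#' Run the full preprocessing funnel
#'
#' Business-hours filter, fixed-OUI exclusion, episode construction and
#' dwell screen in sequence, with stage bookkeeping. Fixed OUIs are
#' learned from the complete (unfiltered) record stream so the
#' out-of-hours rule has power.
#'
#' @param records canonical probe-record tibble for the analysis day.
#' @param window business-hours window.
#' @param gap_threshold_s episode gap threshold (seconds).
#' @param max_dwell_min dwell screen ceiling (minutes).
#' @return list: \code{eligible} (episode tibble), \code{episodes} (all
#'   pre-screen episodes), \code{funnel} (tibble from
#'   [compute_funnel()]), \code{fixed_ouis}, and \code{records} (the
#'   business-hours, OUI-excluded detections).
#' @export
preprocess <- function(records, window = c(10, 22), gap_threshold_s = 600,
                       max_dwell_min = 6) {
  n_total <- nrow(records)
  bh <- filter_business_hours(records, window)
  n_bh <- nrow(bh)
  fixed <- identify_fixed_ouis(records, window)
  kept <- exclude_ouis(bh, fixed)
  det_per_id <- table(kept$device_id)
  n_repeat <- sum(det_per_id > 1)
  episodes <- build_episodes(kept, gap_threshold_s)
  n_dwell <- length(unique(episodes$device_id))
  eligible <- apply_dwell_screen(episodes, max_dwell_min)
  funnel <- compute_funnel(n_total, n_bh, n_repeat, n_dwell, nrow(eligible))
  list(eligible = eligible, episodes = episodes, funnel = funnel,
       fixed_ouis = fixed, records = kept)
}
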