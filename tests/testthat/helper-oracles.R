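# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's vectorised code paths.

# loop-based episode grouping: sort per device, split on gaps, drop
# singleton groups
brute_force_episodes <- function(records, gap_threshold_s = 600) {
  out <- list()
  for (id in sort(unique(records$device_id))) {
    r <- records[records$device_id == id, , drop = FALSE]
    r <- r[order(r$timestamp), , drop = FALSE]
    tt <- as.numeric(r$timestamp)
    grps <- integer(nrow(r))
    g <- 1L
    grps[1] <- g
    if (nrow(r) > 1) {
      for (i in 2:nrow(r)) {
        if (tt[i] - tt[i - 1] > gap_threshold_s) g <- g + 1L
        grps[i] <- g
      }
    }
    for (k in unique(grps)) {
      rg <- r[grps == k, , drop = FALSE]
      if (nrow(rg) >= 2) {
        out[[length(out) + 1]] <- data.frame(
          device_id = id,
          start = min(rg$timestamp),
          end = max(rg$timestamp),
          n_detections = nrow(rg),
          mean_rssi = mean(rg$rssi),
          sd_rssi = stats::sd(rg$rssi)
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(device_id = character(),
                      start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      n_detections = integer(),
                      mean_rssi = numeric(), sd_rssi = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$device_id), , drop = FALSE]
}

# pairwise-comparison AUC: fraction of positive-negative pairs where the
# positive scores higher, ties counting one half
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random small probe log for property tests
random_small_log <- function(n_devices = 3, n_detections = 12,
                             span_s = 3600, tz = "Asia/Tokyo") {
  base <- as.POSIXct("2023-10-28 12:00:00", tz = tz)
  devs <- replicate(n_devices, paste(
    sample(c(0:9, letters[1:6]), 16, replace = TRUE), collapse = ""))
  tibble::tibble(
    timestamp = base + sort(sample(0:span_s, n_detections, replace = TRUE)),
    device_id = sample(devs, n_detections, replace = TRUE),
    oui = "A4C138",
    rssi = as.integer(sample(-90:-40, n_detections, replace = TRUE))
  )
}

# canonical records from explicit times (seconds after noon) and ids
make_records <- function(times_s, ids, rssi = -60, tz = "Asia/Tokyo") {
  base <- as.POSIXct("2023-10-28 12:00:00", tz = tz)
  tibble::tibble(
    timestamp = base + times_s,
    device_id = ids,
    oui = "A4C138",
    rssi = as.integer(rep_len(rssi, length(times_s)))
  )
}

# small, fast scenario for simulator-dependent tests
quiet_scenario <- function(smoker_rate = 6, passerby_rate = 40, ...) {
  sr <- numeric(24); sr[11:22] <- smoker_rate
  pr <- numeric(24); pr[11:22] <- passerby_rate
  scenario_config(smoker_rates = sr, passerby_rates = pr, ...)
}

# scenario whose human arrivals end by 20:00, so no stay can spill past
# the 22:00 business-hours boundary and trip the fixed-OUI rule
midday_scenario <- function(smoker_rate = 6, passerby_rate = 40, ...) {
  sr <- numeric(24); sr[11:20] <- smoker_rate
  pr <- numeric(24); pr[11:20] <- passerby_rate
  scenario_config(smoker_rates = sr, passerby_rates = pr, ...)
}

# high-traffic scenario used for calibration-recovery checks:
# >= 100 true persons per class, with carriage high enough that the
# 30-minute validation window yields ~25-30 classified devices per
# class — below that, the ratio estimator's small-sample (1/D) bias
# dominates and the recovery property is not identifiable
recovery_scenario <- function() {
  sr <- numeric(24); sr[11:21] <- 100   # arrivals end 20:59 so no stay
  pr <- numeric(24); pr[11:21] <- 300   # spills past the 22:00 boundary
  scenario_config(
    smoker_rates = sr, passerby_rates = pr,
    smoker_stay_median_min = 4,
    smoker_carriage = 0.9, passerby_carriage = 0.4
  )
}
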