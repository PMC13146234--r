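#' Received signal strength under a log-distance path-loss model
#'
#' RSSI = p0 - 10 * exponent * log10(distance / d0) + noise. With zero
#' noise this is strictly decreasing in distance; a shadowing draw (dB)
#' can be supplied to add per-probe fading.
#'
#' @param distance_m distance sensor-to-device in metres; must be > 0.
#' @param params path-loss parameter list (\code{p0}, \code{d0},
#'   \code{exponent}); see [scenario_config()].
#' @param noise_db additive noise term in dB (default 0).
#' @return RSSI in dBm (numeric, unrounded).
#' @export
#' @examples
#' pl <- list(p0 = -40, d0 = 1, exponent = 3.5)
#' rssi_at(1, pl)            # -40 at the reference distance
#' rssi_at(2, pl) - rssi_at(1, pl)  # -10 * 3.5 * log10(2)
rssi_at <- function(distance_m, params, noise_db = 0) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0))
    stop("`distance_m` must be positive", call. = FALSE)
  params$p0 - 10 * params$exponent * log10(distance_m / params$d0) + noise_db
}

#' Simulate one person's trajectory
#'
#' Positions are returned at 1-second resolution relative to the person's
#' entry. Smokers perform a bounded random walk inside the dwell zone
#' around the smoking-area centre for the requested duration; passersby
#' cross the corridor laterally in a straight line at a constant speed, so
#' their presence span is corridor length / speed.
#'
#' @param class \code{"smoker"} or \code{"passerby"}.
#' @param config a [scenario_config()].
#' @param duration_s stay duration in seconds. For passersby the duration
#'   is implied by geometry and \code{speed}; this argument is ignored.
#' @param speed walking speed (m/s) for passersby; defaults to the
#'   configured \code{walking_speed}.
#' @return tibble with columns \code{t} (seconds from entry), \code{x},
#'   \code{y} (metres).
#' @export
simulate_trajectory <- function(class, config, duration_s = 360,
                                speed = NULL) {
  tibble::as_tibble(trajectory_points(class, config, duration_s, speed))
}

# internal trajectory engine returning plain vectors (t, x, y)
trajectory_points <- function(class, config, duration_s = 360, speed = NULL) {
  class <- match.arg(class, c("smoker", "passerby"))
  if (class == "smoker") {
    n <- max(2L, ceiling(duration_s) + 1L)
    # bounded random walk: N(0, 0.3 m) steps clipped to the dwell zone
    r0 <- config$dwell_zone_radius * sqrt(stats::runif(1))
    a0 <- stats::runif(1, 0, 2 * pi)
    x <- numeric(n); y <- numeric(n)
    x[1] <- r0 * cos(a0); y[1] <- r0 * sin(a0)
    dx <- stats::rnorm(n - 1, 0, 0.3)
    dy <- stats::rnorm(n - 1, 0, 0.3)
    for (i in 2:n) {
      xi <- x[i - 1] + dx[i - 1]
      yi <- y[i - 1] + dy[i - 1]
      rad <- sqrt(xi^2 + yi^2)
      if (rad > config$dwell_zone_radius) {       # reflect back inside
        xi <- xi * config$dwell_zone_radius / rad
        yi <- yi * config$dwell_zone_radius / rad
      }
      x[i] <- xi; y[i] <- yi
    }
    list(
      t = seq_len(n) - 1,
      x = x + config$smoking_center[1],
      y = y + config$smoking_center[2]
    )
  } else {
    speed <- speed %||% config$walking_speed
    span <- 2 * config$corridor_half_length / speed
    tt <- seq(0, span, by = 1)
    if (tt[length(tt)] < span) tt <- c(tt, span)
    dir <- if (stats::runif(1) < 0.5) 1 else -1
    y0 <- config$corridor_offset +
      stats::runif(1, -config$corridor_width / 2, config$corridor_width / 2)
    list(
      t = tt,
      x = dir * (-config$corridor_half_length + speed * tt),
      y = rep(y0, length(tt))
    )
  }
}

# probe-burst emission over [0, duration_s): burst times from an
# exponential renewal process, burst sizes uniform over the configured range
draw_bursts <- function(duration_s, mean_s, size_range) {
  if (duration_s <= 0) return(numeric(0))
  n_max <- max(10L, ceiling(3 * duration_s / mean_s) + 10L)
  times <- cumsum(stats::rexp(n_max, rate = 1 / mean_s))
  while (length(times) && times[length(times)] < duration_s) {
    times <- c(times, times[length(times)] +
                 cumsum(stats::rexp(n_max, rate = 1 / mean_s)))
  }
  times[times < duration_s]
}

# emit integer-dBm probe records for one device along a trajectory;
# returns plain vectors (epoch seconds) for cheap accumulation
emit_probes <- function(entry, traj, config, device_id, oui) {
  dur <- max(traj$t)
  bt <- draw_bursts(dur, config$inter_burst_mean_s, config$burst_size_range)
  if (!length(bt)) return(NULL)
  sizes <- sample(config$burst_size_range[1]:config$burst_size_range[2],
                  length(bt), replace = TRUE)
  idx <- pmin(floor(bt) + 1L, length(traj$t))
  px <- rep(traj$x[idx], sizes)
  py <- rep(traj$y[idx], sizes)
  tsec <- rep(floor(bt), sizes)
  d <- pmax(sqrt(px^2 + py^2), 0.1)
  rssi <- rssi_at(d, config$path_loss,
                  stats::rnorm(length(d), 0, config$path_loss$shadow_sd))
  rssi <- as.integer(round(rssi))
  keep <- rssi >= config$rssi_floor & rssi <= 0
  if (!any(keep)) return(NULL)
  list(t = floor(as.numeric(entry)) + tsec[keep],   # second resolution
       device_id = rep(device_id, sum(keep)),
       oui = rep(oui, sum(keep)),
       rssi = rssi[keep])
}

# random 12-hex MAC with the given vendor OUI
random_mac <- function(oui) {
  tail6 <- paste(sprintf("%02x", sample(0:255, 3, replace = TRUE)),
                 collapse = "")
  paste0(tolower(oui), tail6)
}

#' Generate a synthetic probe-request log with ground truth
#'
#' Simulates one day at an outdoor smoking area beside a pedestrian
#' corridor. Per class and hour of day, arrivals follow a Poisson process
#' with the configured rate; each person draws a stay duration, a
#' trajectory and (with the class carriage probability) a personal device
#' that emits probe bursts whose RSSI follows the log-distance path-loss
#' model. Fixed roster devices emit around the clock. The output is
#' deterministic given \code{(config, seed)}: one master RNG stream
#' drives arrivals, and each person gets a sub-stream seeded from it.
#'
#' @param config a [scenario_config()].
#' @param seed integer master seed.
#' @return list with \code{log} (canonical probe-record tibble, time
#'   sorted) and \code{truth} (one row per person: \code{person_id},
#'   \code{class}, \code{entry}, \code{exit}, \code{carried},
#'   \code{device_id} (\code{NA} when no device), \code{min_distance_m}),
#'   plus \code{fixed_ouis}, the roster OUIs.
#' @export
generate_scenario <- function(config, seed) {
  validate_scenario_config(config)
  set.seed(seed)
  day0 <- lubridate::ymd_hms(paste(config$date, "00:00:00"), tz = config$tz)

  persons <- list()
  for (cls in c("smoker", "passerby")) {
    rates <- if (cls == "smoker") config$smoker_rates else config$passerby_rates
    for (h in 0:23) {
      n <- stats::rpois(1, rates[h + 1])
      if (n > 0) {
        persons[[length(persons) + 1]] <- tibble::tibble(
          class = cls,
          entry = day0 + (h + stats::runif(n)) * 3600
        )
      }
    }
  }
  logs <- list()
  n_ppl <- 0L
  if (length(persons)) {
    ppl <- dplyr::bind_rows(persons)
    ppl <- ppl[order(ppl$entry), , drop = FALSE]
    n_ppl <- nrow(ppl)
  }
  t_exit <- numeric(n_ppl)
  t_carried <- logical(n_ppl)
  t_dev <- rep(NA_character_, n_ppl)
  t_mind <- numeric(n_ppl)
  if (n_ppl) {
    sub_seeds <- sample.int(.Machine$integer.max, n_ppl)
    for (i in seq_len(n_ppl)) {
      set.seed(sub_seeds[i])
      cls <- ppl$class[i]
      if (cls == "smoker") {
        dur <- stats::rlnorm(1, log(config$smoker_stay_median_min * 60),
                             config$smoker_stay_sdlog)
        traj <- trajectory_points("smoker", config, duration_s = dur)
        carried <- stats::runif(1) < config$smoker_carriage
      } else {
        spd <- config$walking_speed *
          exp(stats::rnorm(1, 0, config$passerby_speed_sdlog))
        traj <- trajectory_points("passerby", config, speed = spd)
        dur <- max(traj$t)
        carried <- stats::runif(1) < config$passerby_carriage
      }
      if (carried) {
        oui <- sample(phone_oui_pool(), 1)
        mac <- random_mac(oui)
        t_dev[i] <- anonymize_identifier(mac, config$salt)
        probes <- emit_probes(ppl$entry[i], traj, config, t_dev[i], oui)
        if (!is.null(probes)) logs[[length(logs) + 1]] <- probes
      }
      t_exit[i] <- as.numeric(ppl$entry[i]) + dur
      t_carried[i] <- carried
      t_mind[i] <- min(sqrt(traj$x^2 + traj$y^2))
    }
  }

  # fixed infrastructure devices transmit across all 24 hours
  fd <- config$fixed_devices
  if (nrow(fd)) {
    fd_seeds <- sample.int(.Machine$integer.max, nrow(fd))
    for (j in seq_len(nrow(fd))) {
      set.seed(fd_seeds[j])
      mac <- paste0(tolower(fd$oui[j]), sprintf("%06x", j))
      dev_id <- anonymize_identifier(mac, config$salt)
      traj <- list(t = c(0, 86400), x = rep(fd$x[j], 2), y = rep(fd$y[j], 2))
      cfg_j <- config
      cfg_j$inter_burst_mean_s <- fd$inter_burst_mean_s[j]
      probes <- emit_probes(day0, traj, cfg_j, dev_id, toupper(fd$oui[j]))
      if (!is.null(probes)) logs[[length(logs) + 1]] <- probes
    }
  }

  if (length(logs)) {
    log <- tibble::tibble(
      timestamp = as.POSIXct(unlist(lapply(logs, `[[`, "t")),
                             origin = "1970-01-01", tz = config$tz),
      device_id = unlist(lapply(logs, `[[`, "device_id")),
      oui = unlist(lapply(logs, `[[`, "oui")),
      rssi = unlist(lapply(logs, `[[`, "rssi"))
    )
    log <- log[order(log$timestamp, log$device_id, log$rssi), , drop = FALSE]
  } else {
    log <- empty_probe_log(config$tz)
  }
  truth <- if (n_ppl) tibble::tibble(
    person_id = sprintf("p%05d", seq_len(n_ppl)),
    class = ppl$class,
    entry = ppl$entry,
    exit = as.POSIXct(t_exit, origin = "1970-01-01", tz = config$tz),
    carried = t_carried,
    device_id = t_dev,
    min_distance_m = t_mind
  ) else tibble::tibble(
    person_id = character(), class = character(),
    entry = as.POSIXct(character(), tz = config$tz),
    exit = as.POSIXct(character(), tz = config$tz),
    carried = logical(), device_id = character(),
    min_distance_m = numeric()
  )
  list(log = log, truth = truth, fixed_ouis = toupper(unique(fd$oui)))
}

#' Write simulator ground truth to CSV
#'
#' @param truth ground-truth tibble from [generate_scenario()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$entry <- format_probe_time(out$entry)
  out$exit <- format_probe_time(out$exit)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read simulator ground truth from CSV
#'
#' @param path file written by [write_ground_truth()].
#' @param tz timezone for the parsed entry/exit times.
#' @return ground-truth tibble.
#' @export
read_ground_truth <- function(path, tz = "Asia/Tokyo") {
  df <- utils::read.csv(path, colClasses = "character")
  tibble::tibble(
    person_id = df$person_id,
    class = df$class,
    entry = lubridate::with_tz(lubridate::ymd_hms(df$entry), tz),
    exit = lubridate::with_tz(lubridate::ymd_hms(df$exit), tz),
    carried = df$carried == "TRUE",
    device_id = ifelse(df$device_id == "", NA_character_, df$device_id),
    min_distance_m = as.numeric(df$min_distance_m)
  )
}
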