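test_that("null scenario yields an empty log and empty truth", {
  cfg <- scenario_config(smoker_rates = numeric(24),
                         passerby_rates = numeric(24),
                         fixed_devices = default_fixed_devices()[0, ])
  sim <- generate_scenario(cfg, 7)
  expect_equal(nrow(sim$log), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_named(sim$log, c("timestamp", "device_id", "oui", "rssi"))
})

test_that("the same (config, seed) reproduces the log byte for byte", {
  cfg <- quiet_scenario()
  a <- generate_scenario(cfg, 11)
  b <- generate_scenario(cfg, 11)
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_probe_log(a$log, f1)
  write_probe_log(b$log, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different realisation
  expect_false(identical(generate_scenario(cfg, 12)$log, a$log))
})

test_that("Poisson arrivals give the configured expected total", {
  pr <- numeric(24); pr[11:20] <- 100          # 100/h for 10 hours
  cfg <- scenario_config(smoker_rates = numeric(24), passerby_rates = pr,
                         passerby_carriage = 0,
                         fixed_devices = default_fixed_devices()[0, ])
  sim <- generate_scenario(cfg, 123)
  # total persons ~ Poisson(1000): mean 1000, SD sqrt(1000)
  expect_lt(abs(nrow(sim$truth) - 1000), 3 * sqrt(1000))
})

test_that("scenario config invariants are enforced with field names", {
  expect_error(scenario_config(smoker_rates = rep(-1, 24)), "smoker_rates")
  expect_error(scenario_config(passerby_carriage = 1.5), "passerby_carriage")
  expect_error(scenario_config(path_loss = list(p0 = -40, d0 = 0,
                                                exponent = 2, shadow_sd = 1)),
               "d0")
  expect_error(scenario_config(assessment_radius = -1), "assessment_radius")
})

test_that("rssi_at follows the log-distance closed form", {
  pl <- list(p0 = -40, d0 = 1, exponent = 3.5, shadow_sd = 0)
  expect_equal(rssi_at(1, pl), -40)                       # reference point
  # doubling distance drops RSSI by 10 * n * log10(2)
  expect_equal(rssi_at(2, pl) - rssi_at(1, pl), -10 * 3.5 * log10(2))
  expect_equal(rssi_at(8, pl) - rssi_at(4, pl), -10 * 3.5 * log10(2))
  expect_error(rssi_at(0, pl), "positive")
  expect_error(rssi_at(-3, pl), "positive")
})

test_that("rssi_at is strictly monotone decreasing in distance", {
  pl <- list(p0 = -40, d0 = 1, exponent = 2.7)
  d <- seq(0.5, 40, by = 0.5)
  expect_true(all(diff(rssi_at(d, pl)) < 0))
})

test_that("noisy RSSI draws average to the noiseless value", {
  pl <- list(p0 = -40, d0 = 1, exponent = 3.5, shadow_sd = 4)
  set.seed(99)
  n <- 10000
  draws <- rssi_at(7, pl, noise_db = rnorm(n, 0, pl$shadow_sd))
  expect_lt(abs(mean(draws) - rssi_at(7, pl)), 3 * pl$shadow_sd / sqrt(n))
})

test_that("passerby trajectories traverse the corridor at walking speed", {
  cfg <- scenario_config()
  set.seed(5)
  traj <- simulate_trajectory("passerby", cfg, speed = 1.2)
  # 30 m corridor at 1.2 m/s: 25 s presence span
  expect_equal(max(traj$t), 25)
  expect_equal(abs(traj$x[1]), cfg$corridor_half_length)
  expect_true(all(abs(traj$y - cfg$corridor_offset) <= cfg$corridor_width / 2))
})

test_that("smoker trajectories stay inside the dwell zone", {
  cfg <- scenario_config()
  set.seed(6)
  for (rep in 1:5) {
    traj <- simulate_trajectory("smoker", cfg, duration_s = 300)
    d <- sqrt((traj$x - cfg$smoking_center[1])^2 +
                (traj$y - cfg$smoking_center[2])^2)
    expect_true(all(d <= cfg$dwell_zone_radius + 1e-9))
  }
})

test_that("simulated smoker stays recover the configured log-normal median", {
  sr <- numeric(24); sr[11:22] <- 90   # ~1080 smokers
  cfg <- scenario_config(smoker_rates = sr, passerby_rates = numeric(24),
                         smoker_carriage = 0,
                         fixed_devices = default_fixed_devices()[0, ])
  sim <- generate_scenario(cfg, 31)
  expect_gte(nrow(sim$truth), 1000)
  stays_min <- as.numeric(difftime(sim$truth$exit, sim$truth$entry,
                                   units = "mins"))
  expect_lt(abs(stats::median(stays_min) - 6) / 6, 0.10)
})

test_that("every emitted record traces to ground truth or the fixed roster", {
  cfg <- quiet_scenario()
  sim <- generate_scenario(cfg, 21)
  truth_devs <- sim$truth$device_id[!is.na(sim$truth$device_id)]
  fixed_recs <- sim$log$oui %in% sim$fixed_ouis
  expect_true(all(sim$log$device_id[!fixed_recs] %in% truth_devs))
  # device id present iff carried
  expect_identical(is.na(sim$truth$device_id), !sim$truth$carried)
  # exit never precedes entry; log is time sorted
  expect_true(all(sim$truth$exit >= sim$truth$entry))
  expect_true(!is.unsorted(sim$log$timestamp))
})

test_that("fixed roster devices emit across all 24 hours", {
  cfg <- scenario_config(smoker_rates = numeric(24),
                         passerby_rates = numeric(24))
  sim <- generate_scenario(cfg, 3)
  hrs <- sort(unique(lubridate::hour(sim$log$timestamp)))
  expect_equal(hrs, 0:23)
  expect_true(all(sim$log$oui %in% sim$fixed_ouis))
})

test_that("episode mean RSSI separates the behavioral classes", {
  cfg <- quiet_scenario(smoker_rate = 10, passerby_rate = 60)
  sim <- generate_scenario(cfg, 17)
  pp <- preprocess(sim$log)
  lab <- sim$truth$class[match(pp$eligible$device_id, sim$truth$device_id)]
  m <- tapply(pp$eligible$mean_rssi, lab, mean)
  # smokers linger nearer the sensor: clearly higher mean RSSI
  expect_gt(m[["smoker"]], m[["passerby"]] + 10)
  # the band rule achieves above-chance smoker recall on simulated data
  cl <- classify_primary(pp$eligible$mean_rssi)
  recall <- mean(cl[lab == "smoker"] == "smoker")
  expect_gt(recall, 0.5)
})

test_that("carriage probability controls the person/device ratio", {
  pr <- numeric(24); pr[11:22] <- 60            # ~720 passersby
  cfg <- scenario_config(smoker_rates = numeric(24), passerby_rates = pr,
                         passerby_carriage = 0.135)
  sim <- generate_scenario(cfg, 8)
  n <- nrow(sim$truth)
  expect_gte(n, 500)
  carried <- sum(sim$truth$carried)
  ratio <- n / carried
  p <- 0.135
  # binomial sampling error on the carried count, propagated to 1/p
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(carried - n * p), 3 * se)
  expect_lt(abs(ratio - 1 / p) / (1 / p), 0.25)
})
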