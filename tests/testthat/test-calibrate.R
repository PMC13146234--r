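tz <- "Asia/Tokyo"

test_that("capture ratios and multipliers follow the validation arithmetic", {
  r <- compute_ratios(validation_counts(14, 207, 7, 28))
  expect_equal(r$capture_ratio[["smoker"]], 0.5)
  expect_equal(r$capture_pct[["smoker"]], 50)
  expect_equal(r$multiplier[["smoker"]], 2.0)
  expect_equal(r$capture_pct[["passerby"]], 13.5)
  expect_equal(r$multiplier[["passerby"]], 7.4)
  # identity calibration
  r1 <- compute_ratios(validation_counts(10, 20, 10, 20))
  expect_equal(unname(r1$capture_ratio), c(1, 1))
  expect_equal(unname(r1$multiplier), c(1, 1))
})

test_that("zero counts make calibration undefined, naming the class", {
  expect_error(compute_ratios(validation_counts(0, 207, 7, 28)), "smoker")
  expect_error(compute_ratios(validation_counts(14, 207, 7, 0)), "passerby")
  expect_error(validation_counts(-1, 207, 7, 28), ">= 0")
})

test_that("day totals scale devices by the one-decimal multiplier", {
  r <- compute_ratios(validation_counts(14, 207, 7, 28))
  est <- estimate_day_totals(c(smoker = 131, passerby = 528), r)
  expect_equal(est$persons[est$class == "smoker"], 262)
  expect_equal(est$persons[est$class == "passerby"], 3907)  # 528*7.4 = 3907.2
  est0 <- estimate_day_totals(c(smoker = 0, passerby = 0), r)
  expect_equal(est0$persons, c(0, 0))
  expect_error(estimate_day_totals(c(smoker = 1), r), "named")
  expect_error(estimate_day_totals(c(smoker = 1, passerby = 1), list()),
               "compute_ratios")
})

test_that("pre-rounding person estimates are linear in device counts", {
  r <- compute_ratios(validation_counts(14, 207, 7, 28))
  d1 <- c(smoker = 57, passerby = 211)
  e1 <- estimate_day_totals(d1, r)
  e2 <- estimate_day_totals(2 * d1, r)
  # doubling devices doubles the unrounded estimate; rounding adds at
  # most one person of slack
  expect_lte(max(abs(e2$persons - 2 * e1$persons)), 1)
})

test_that("rounded day totals reconstruct the eligible episode count", {
  # regression of the arithmetic conventions: round(262/2.0) +
  # round(3907/7.4) gives back the 659 eligible episodes
  expect_equal(round_half_up(262 / 2.0) + round_half_up(3907 / 7.4), 659)
})

test_that("hourly profiles concentrate, flatten and sum as expected", {
  r <- compute_ratios(validation_counts(14, 207, 7, 28))
  base <- as.POSIXct("2023-10-28 13:30:00", tz = tz)
  one_hour <- tibble::tibble(
    start = base + 1:10,
    primary_label = factor(rep("smoker", 10),
                           levels = c("smoker", "passerby", "unclassified"))
  )
  h <- hourly_profile(one_hour, r)
  hs <- h[h$class == "smoker", ]
  expect_equal(hs$persons[hs$hour == 13], 20)          # full day estimate
  expect_true(all(hs$persons[hs$hour != 13] == 0))

  flat <- tibble::tibble(
    start = as.POSIXct("2023-10-28 10:30:00", tz = tz) + 3600 * (0:11),
    primary_label = factor(rep("passerby", 12),
                           levels = c("smoker", "passerby", "unclassified"))
  )
  hf <- hourly_profile(flat, r)
  hp <- hf[hf$class == "passerby" & hf$hour %in% 10:21, ]
  expect_equal(length(unique(round(hp$persons, 6))), 1)  # flat profile
  # hourly persons sum to the rounded day total per class
  expect_equal(sum(hf$persons[hf$class == "passerby"]),
               round_half_up(12 * 7.4))
})

test_that("simulated bimodal smoker arrivals reappear in the hourly profile", {
  sr <- numeric(24); sr[c(13, 17)] <- 60    # peaks at hours 12 and 16
  sr[c(11, 12, 14, 15, 16, 18:22)] <- 5
  cfg <- scenario_config(smoker_rates = sr, passerby_rates = numeric(24),
                         smoker_carriage = 1)
  sim <- generate_scenario(cfg, 66)
  pp <- preprocess(sim$log)
  cl <- classify_episodes(pp$eligible)
  r <- compute_ratios(validation_counts(14, 207, 7, 28))
  h <- hourly_profile(cl, r)
  hs <- h[h$class == "smoker", ]
  top2 <- hs$hour[order(-hs$devices)][1:2]
  expect_setequal(top2, c(12, 16))
})

test_that("sensitivity grid: identity row equals baseline, effects monotone", {
  sim <- generate_scenario(quiet_scenario(smoker_rate = 10,
                                          passerby_rate = 60), 83)
  pp <- preprocess(sim$log)
  window <- as.POSIXct(c("2023-10-28 15:00:00", "2023-10-28 15:30:00"),
                       tz = tz)
  manual <- manual_counts_from_truth(sim$truth, window)
  tab <- sensitivity_analysis(pp$episodes, manual, window)
  expect_equal(nrow(tab), 25)

  base <- tab[tab$dwell_factor == 1 & tab$rssi_factor == 1, ]
  expect_true(base$valid)
  expect_equal(base$smoker_pct_change, 0)
  expect_equal(base$passerby_pct_change, 0)

  # baseline row reproduces an independent baseline run exactly
  cl <- classify_episodes(apply_dwell_screen(pp$episodes, 6))
  wdev <- c(smoker = sum(cl$primary_label == "smoker" &
                           cl$start >= window[1] & cl$start < window[2]),
            passerby = sum(cl$primary_label == "passerby" &
                             cl$start >= window[1] & cl$start < window[2]))
  r0 <- compute_ratios(validation_counts(manual[["smoker"]],
                                         manual[["passerby"]],
                                         wdev[["smoker"]],
                                         wdev[["passerby"]]))
  est0 <- estimate_day_totals(
    c(smoker = sum(cl$primary_label == "smoker"),
      passerby = sum(cl$primary_label == "passerby")), r0)
  expect_equal(base$smoker_total, est0$persons[est0$class == "smoker"])
  expect_equal(base$passerby_total, est0$persons[est0$class == "passerby"])

  # relaxing the dwell screen never reduces eligible episodes, so the
  # classified device counts are nondecreasing in the dwell factor
  for (rf in unique(tab$rssi_factor)) {
    sub <- tab[tab$rssi_factor == rf & tab$valid, ]
    sub <- sub[order(sub$dwell_factor), ]
    if (nrow(sub) > 1) {
      expect_true(all(diff(sub$smoker_devices) >= 0))
      expect_true(all(diff(sub$passerby_devices) >= 0))
    }
  }
})

test_that("widening the smoker band cannot lose smoker devices", {
  sim <- generate_scenario(quiet_scenario(), 19)
  pp <- preprocess(sim$log)
  elig <- apply_dwell_screen(pp$episodes, 6)
  narrow <- classify_episodes(elig, c(-75, -46), c(-88, -76))
  wide <- classify_episodes(elig, c(-80, -40), c(-88, -81))
  expect_gte(sum(wide$primary_label == "smoker"),
             sum(narrow$primary_label == "smoker"))
})

test_that("invalid perturbations are flagged, not skipped", {
  expect_error(validate_bands(c(-75, -46), c(-88, -70)), "overlap")
  sim <- generate_scenario(quiet_scenario(smoker_rate = 2,
                                          passerby_rate = 5), 91)
  pp <- preprocess(sim$log)
  window <- as.POSIXct(c("2023-10-28 03:00:00", "2023-10-28 03:30:00"),
                       tz = tz)     # empty window: zero devices
  manual <- c(smoker = 3, passerby = 10)
  tab <- sensitivity_analysis(pp$episodes, manual, window,
                              dwell_factors = 1, rssi_factors = 1)
  expect_false(tab$valid)
  expect_equal(tab$reason, "zero_window_devices")
})
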