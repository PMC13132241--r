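quick_config <- function(...) {
  sim_config(n_participants = 3, stage_duration_s = 180, rest_duration_s = 60,
             recovery_between_s = 60, final_recovery_s = 60, ...)
}

test_that("protocol trajectory settles on each stage target", {
  cfg <- sim_config()
  traj <- simulate_protocol_hr(age = 20, cfg)
  # within a stage, 5 time constants after its start the level is within
  # 1 beat/min of the target
  runs <- rle(traj$target)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in which(runs$lengths >= 5 * cfg$kinetics_tau_s)) {
    settled <- traj$hr_true[(starts[k] + 5 * cfg$kinetics_tau_s):ends[k]]
    expect_true(all(abs(settled - runs$values[k]) < 1))
  }
  # 40% stage of a 20-year-old settles near 80 beats/min
  stage1 <- traj$hr_true[traj$target == 0.40 * 200]
  expect_equal(stage1[length(stage1)], 80, tolerance = 0.1)
})

test_that("transitions are monotone between consecutive targets", {
  traj <- simulate_protocol_hr(age = 30, sim_config())
  runs <- rle(traj$target)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$lengths)[-1]) {
    seg <- traj$hr_true[starts[k]:ends[k]]
    dir <- sign(runs$values[k] - runs$values[k - 1])
    expect_true(all(dir * diff(seg) >= -1e-9))
  }
})

test_that("stage targets below resting heart rate are rejected", {
  expect_error(simulate_protocol_hr(20, sim_config(rest_hr = 90)),
               class = "hragree_config_error")
})

test_that("noise-free devices reproduce the true trajectory exactly", {
  cfg <- quick_config(mu = 0, tau2 = 0, sigma2 = 0, criterion_jitter_sd = 0,
                      hetero_slope = 0)
  traj <- simulate_protocol_hr(25, cfg)
  pair <- simulate_device_pair(traj, "P1", 0, cfg, seed = 4)
  truth <- approx(traj$time_s, traj$hr_true, xout = pair$criterion$timestamp)$y
  expect_equal(pair$criterion$hr, truth, tolerance = 1e-12)
  truth_idx <- approx(traj$time_s, traj$hr_true, xout = pair$index$timestamp)$y
  expect_equal(pair$index$hr, truth_idx, tolerance = 1e-12)
})

test_that("epoch-level variance of differences matches the configured components", {
  cfg <- sim_config(n_participants = 40, hetero_slope = 0, spike_rate_per_min = 0,
                    missing_epoch_prob = 0, seed = 11)
  st <- generate_study(cfg)
  p <- pair_epochs(epoch_aggregate(st$index, 5), epoch_aggregate(st$criterion, 5))
  target_sd <- sqrt(cfg$tau2 + cfg$sigma2)
  expect_lt(abs(sd(p$difference) - target_sd) / target_sd, 0.05)
  expect_equal(mean(p$difference), cfg$mu, tolerance = 0.3)
})

test_that("heteroscedastic noise widens dispersion at higher intensities", {
  cfg <- sim_config(n_participants = 10, spike_rate_per_min = 0,
                    missing_epoch_prob = 0, seed = 19) # hetero_slope default 0.02
  st <- generate_study(cfg)
  p <- pair_epochs(epoch_aggregate(st$index, 5), epoch_aggregate(st$criterion, 5)) |>
    add_zones(st$participants)
  sds <- p |>
    dplyr::group_by(zone) |>
    dplyr::summarise(sd = sd(difference))
  expect_gt(sds$sd[sds$zone == "vigorous"], sds$sd[sds$zone == "rest"])
})

test_that("spike injection is deterministic, optional, and isolated", {
  cfg <- quick_config(seed = 2)
  traj <- simulate_protocol_hr(22, cfg)
  pair <- simulate_device_pair(traj, "P1", 0, cfg, seed = 6)
  none <- inject_spike_artifacts(pair$criterion, rate_per_min = 0, seed = 1)
  expect_identical(none$series, pair$criterion)
  expect_length(none$positions, 0)

  a <- inject_spike_artifacts(pair$criterion, 1, 15, seed = 42)
  b <- inject_spike_artifacts(pair$criterion, 1, 15, seed = 42)
  expect_identical(a$series, b$series)
  expect_identical(a$positions, b$positions)
  expect_gt(length(a$positions), 0)
  expect_true(all(diff(sort(a$positions)) > 1))
  # neighbours untouched
  untouched <- setdiff(seq_len(nrow(pair$criterion)), a$positions)
  expect_identical(a$series$hr[untouched], pair$criterion$hr[untouched])
  expect_warning(inject_spike_artifacts(pair$criterion, 1, 8, seed = 1),
                 "below 10")
})

test_that("spike filter removes exactly the injected positions on a smooth trajectory", {
  cfg <- quick_config(criterion_jitter_sd = 0.3, kinetics_tau_s = 70, seed = 7)
  traj <- simulate_protocol_hr(24, cfg)
  pair <- simulate_device_pair(traj, "P1", 0, cfg, seed = 9)
  inj <- inject_spike_artifacts(pair$criterion, rate_per_min = 1.5,
                                magnitude_bpm = 20, seed = 10)
  cleaned <- suppressMessages(remove_spike_artifacts(inj$series))
  removed_ts <- setdiff(inj$series$timestamp, cleaned$timestamp)
  expect_setequal(removed_ts, inj$series$timestamp[inj$positions])
})

test_that("study generation is a pure function of config and seed", {
  cfg <- quick_config(seed = 33)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$index, s2$index)
  expect_identical(s1$criterion, s2$criterion)
  expect_identical(s1$participants, s2$participants)
})

test_that("study files land on disk with the configured cohort size", {
  dir <- file.path(tempdir(), "genstudy-test")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- quick_config(seed = 12)
  st <- generate_study(cfg, dir = dir)
  expect_setequal(list.files(dir),
                  c("participants.csv", "index_hr.csv", "criterion_hr.csv",
                    "manifest.json"))
  expect_equal(nrow(st$participants), 3)
  expect_equal(dplyr::n_distinct(st$index$participant_id), 3)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 12)
  expect_equal(manifest$epoch_level_sigma2, 26.73)
  expect_true(all(st$participants$age >= 18 & st$participants$age <= 65))
})

test_that("index epoch dropouts occur at about the configured rate", {
  cfg <- sim_config(n_participants = 6, missing_epoch_prob = 0.2,
                    spike_rate_per_min = 0, seed = 27)
  st <- generate_study(cfg)
  cfg0 <- sim_config(n_participants = 6, missing_epoch_prob = 0,
                     spike_rate_per_min = 0, seed = 27)
  st0 <- generate_study(cfg0)
  n_with <- nrow(epoch_aggregate(st$index, 5))
  n_without <- nrow(epoch_aggregate(st0$index, 5))
  frac <- 1 - n_with / n_without
  expect_lt(abs(frac - 0.2), 0.03)
})

test_that("direct epoch-difference simulation hits its moments", {
  tab <- simulate_epoch_differences(50, 200, mu = 1, tau2 = 2, sigma2 = 9,
                                    seed = 3)
  expect_equal(nrow(tab), 50 * 200)
  expect_equal(mean(tab$difference), 1, tolerance = 0.15)
  expect_equal(var(tab$difference), 11, tolerance = 0.8)
  expect_identical(tab, simulate_epoch_differences(50, 200, mu = 1, tau2 = 2,
                                                   sigma2 = 9, seed = 3))
})
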