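# Synthetic two-device heart-rate study generator.
#
# Emulates a graded treadmill protocol: rest, five exercise stages
# targeting fixed percentages of age-predicted HRmax with first-order
# heart-rate kinetics, and recovery. The criterion device samples the true
# trajectory at 1 Hz with small jitter; the index device samples at
# irregular intervals with a participant-level bias, AR(1) noise whose
# dispersion grows with heart rate, optional spike artefacts, and
# epoch-level dropouts.

#' Simulation configuration
#'
#' Builds and validates the full parameter set for the synthetic study.
#' The defaults reproduce the statistical structure the agreement model
#' assumes: a device bias of `mu` with participant-level spread `tau2`,
#' and within-participant noise whose 5-s-epoch-level variance equals
#' `sigma2` (sample-level noise is inflated to offset the averaging of
#' several samples per epoch; see [effective_epoch_factor()]).
#'
#' @param n_participants Number of participants. Default 40.
#' @param age_mean,age_sd Age distribution in years (normal, truncated to
#'   18-65). Defaults 23.8 and 3.6.
#' @param stage_targets Exercise-stage targets as %HRmax, strictly
#'   increasing. Default `c(40, 55, 65, 75, 85)`.
#' @param stage_duration_s Steady-state stage length, seconds. Default 210.
#' @param rest_duration_s,recovery_between_s,final_recovery_s Rest before
#'   the first stage, recovery between stages, and final recovery,
#'   seconds. Defaults 240, 120, 300.
#' @param rest_hr Resting heart rate, beats/min. Default 65.
#' @param kinetics_tau_s Time constant of the first-order heart-rate
#'   response to a change in demand, seconds. Default 35.
#' @param mu True device bias (index minus criterion), beats/min.
#'   Default -0.03.
#' @param tau2 Between-participant bias variance, beats^2/min^2.
#'   Default 0.61.
#' @param sigma2 Within-participant noise variance at the 5-s epoch level,
#'   beats^2/min^2. Default 26.73.
#' @param phi AR(1) coefficient of the index-device noise, per sample,
#'   `|phi| < 1`. Default 0.6.
#' @param hetero_slope Relative increase in noise SD per beats/min above
#'   `rest_hr` (0 = homoscedastic). Default 0.02.
#' @param criterion_rate_hz Criterion sampling rate. Default 1.
#' @param criterion_jitter_sd Criterion measurement noise SD, beats/min.
#'   Default 0.5.
#' @param index_gap_range_s Range of the uniform jitter on index
#'   inter-sample gaps, seconds. Default `c(1, 2)` (0.5-1 Hz).
#' @param spike_rate_per_min Criterion spike-artefact rate. Default 0.5.
#' @param spike_magnitude_bpm Spike displacement, beats/min. Default 15.
#' @param missing_epoch_prob Probability an index epoch is dropped
#'   entirely. Default 0.02.
#' @param epoch_s Epoch length the analysis will use (needed for the
#'   noise calibration). Default 5.
#' @param calibrate_epoch_variance Interpret `sigma2` at the epoch level
#'   (default `TRUE`); with `FALSE` it is the raw sample-level variance.
#' @param seed Integer seed. Default 1.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 40,
                       age_mean = 23.8, age_sd = 3.6,
                       stage_targets = c(40, 55, 65, 75, 85),
                       stage_duration_s = 210,
                       rest_duration_s = 240,
                       recovery_between_s = 120,
                       final_recovery_s = 300,
                       rest_hr = 65,
                       kinetics_tau_s = 35,
                       mu = -0.03, tau2 = 0.61, sigma2 = 26.73, phi = 0.6,
                       hetero_slope = 0.02,
                       criterion_rate_hz = 1,
                       criterion_jitter_sd = 0.5,
                       index_gap_range_s = c(1, 2),
                       spike_rate_per_min = 0.5,
                       spike_magnitude_bpm = 15,
                       missing_epoch_prob = 0.02,
                       epoch_s = 5,
                       calibrate_epoch_variance = TRUE,
                       seed = 1L) {
  stopifnot(n_participants >= 1, age_sd >= 0,
            all(diff(stage_targets) > 0),
            stage_duration_s > 0, rest_hr > 0, kinetics_tau_s > 0,
            tau2 >= 0, sigma2 >= 0, abs(phi) < 1, hetero_slope >= 0,
            criterion_rate_hz > 0, criterion_jitter_sd >= 0,
            length(index_gap_range_s) == 2, all(index_gap_range_s > 0),
            diff(index_gap_range_s) >= 0,
            spike_rate_per_min >= 0,
            missing_epoch_prob >= 0, missing_epoch_prob <= 1,
            epoch_s > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Variance-shrink factor of epoch means of AR(1) noise
#'
#' The mean of `m` consecutive AR(1) samples with unit marginal variance
#' has variance `f(m, phi) = (m + 2 * sum_{j<m} (m - j) phi^j) / m^2`.
#' For the generator's jittered sampling, `m` is the expected number of
#' index samples per epoch and the factor is interpolated between the
#' bracketing integers. The generator divides its sample-level noise SD by
#' `sqrt(f)` so that epoch-level noise variance equals the configured
#' `sigma2`.
#'
#' @param config A `sim_config`.
#' @return The scalar shrink factor in (0, 1].
#' @export
effective_epoch_factor <- function(config) {
  mean_gap <- mean(config$index_gap_range_s)
  m <- config$epoch_s / mean_gap
  f_int <- function(k) {
    if (k <= 1) return(1)
    j <- seq_len(k - 1)
    (k + 2 * sum((k - j) * config$phi^j)) / k^2
  }
  lo <- floor(m); hi <- ceiling(m)
  if (lo == hi) return(f_int(lo))
  w <- m - lo
  (1 - w) * f_int(lo) + w * f_int(hi)
}

#' Simulate a participant's true heart-rate trajectory
#'
#' Piecewise protocol (rest, graded stages at `stage_targets` %HRmax with
#' brief recoveries, final recovery) with first-order kinetics: the heart
#' rate relaxes toward the current target with time constant
#' `kinetics_tau_s`. Deterministic (no noise).
#'
#' @param age Participant age in years (sets HRmax = 220 - age).
#' @param config A `sim_config`.
#' @return A tibble `time_s` (per-second), `hr_true`, `target`.
#' @export
simulate_protocol_hr <- function(age, config) {
  hrmax <- predicted_hrmax(age)
  stage_hr <- config$stage_targets / 100 * hrmax
  if (any(stage_hr <= config$rest_hr)) {
    rlang::abort("a stage target implies a heart rate at or below rest_hr",
                 class = "hragree_config_error")
  }
  recovery_hr <- config$rest_hr + 10
  segs <- list(c(config$rest_duration_s, config$rest_hr))
  for (k in seq_along(stage_hr)) {
    segs <- c(segs, list(c(config$stage_duration_s, stage_hr[k])))
    if (k < length(stage_hr)) {
      segs <- c(segs, list(c(config$recovery_between_s, recovery_hr)))
    }
  }
  segs <- c(segs, list(c(config$final_recovery_s, config$rest_hr)))
  durations <- vapply(segs, `[`, 0, 1)
  targets <- vapply(segs, `[`, 0, 2)
  total_s <- sum(durations)
  target_t <- rep(targets, times = durations)

  hr <- numeric(total_s)
  decay <- exp(-1 / config$kinetics_tau_s)
  prev <- config$rest_hr
  for (t in seq_len(total_s)) {
    prev <- target_t[t] + (prev - target_t[t]) * decay
    hr[t] <- prev
  }
  tibble::tibble(time_s = seq_len(total_s) - 1, hr_true = hr, target = target_t)
}

#' Simulate one participant's paired device recordings
#'
#' The criterion device samples the true trajectory at
#' `criterion_rate_hz` with independent N(0, `criterion_jitter_sd`^2)
#' noise. The index device samples at irregular gaps (uniform on
#' `index_gap_range_s`) and reads
#' `true + mu + b_i + e_t`, where `b_i` is the participant's bias offset
#' and `e_t` is AR(1) noise whose marginal SD follows the configured
#' epoch-calibrated `sigma2` scaled by
#' `1 + hetero_slope * max(0, hr - rest_hr)`.
#'
#' @param true_hr Trajectory tibble from [simulate_protocol_hr()].
#' @param participant_id Identifier stamped on both series.
#' @param participant_bias The participant's bias offset `b_i`, beats/min.
#' @param config A `sim_config`.
#' @param seed Optional integer seed (set it for standalone determinism).
#' @return A list with heart-rate tibbles `index` and `criterion`.
#' @export
simulate_device_pair <- function(true_hr, participant_id, participant_bias,
                                 config, seed = NULL) {
  if (nrow(true_hr) == 0L) rlang::abort("empty trajectory", class = "hragree_domain_error")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  total_s <- max(true_hr$time_s)
  hr_at <- stats::approxfun(true_hr$time_s, true_hr$hr_true, rule = 2)

  t_crit <- seq(0, total_s, by = 1 / config$criterion_rate_hz)
  criterion <- tibble::tibble(
    participant_id = participant_id,
    timestamp = t_crit,
    hr = hr_at(t_crit) + stats::rnorm(length(t_crit), 0, config$criterion_jitter_sd)
  )

  # irregular index sampling: renewal process with uniform gaps
  n_max <- ceiling(total_s / config$index_gap_range_s[1]) + 1L
  gaps <- stats::runif(n_max, config$index_gap_range_s[1], config$index_gap_range_s[2])
  t_idx <- cumsum(gaps)
  t_idx <- t_idx[t_idx <= total_s]

  base_sd <- sqrt(config$sigma2)
  if (config$calibrate_epoch_variance) {
    base_sd <- base_sd / sqrt(effective_epoch_factor(config))
  }
  n <- length(t_idx)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, 0, sqrt(1 - config$phi^2))
  for (t in seq_len(n - 1)) z[t + 1] <- config$phi * z[t] + innov[t]
  true_at_idx <- hr_at(t_idx)
  sd_t <- base_sd * (1 + config$hetero_slope * pmax(0, true_at_idx - config$rest_hr))
  index <- tibble::tibble(
    participant_id = participant_id,
    timestamp = t_idx,
    hr = true_at_idx + config$mu + participant_bias + sd_t * z
  )
  list(index = index, criterion = criterion)
}

#' Inject isolated spike artefacts into a heart-rate series
#'
#' Displaces randomly chosen interior, non-adjacent samples by
#' `+/- magnitude_bpm`, leaving their neighbours untouched, so the spike
#' filter's detection rule can be exercised against known positions.
#'
#' @param series Heart-rate tibble for one participant, time-sorted.
#' @param rate_per_min Expected spikes per minute of recording.
#' @param magnitude_bpm Displacement magnitude; a warning is issued below
#'   10 beats/min since the default filter threshold will not catch such
#'   spikes. Default 15.
#' @param seed Optional integer seed.
#' @return A list: `series` (modified tibble) and `positions` (row indices
#'   of the displaced samples).
#' @export
inject_spike_artifacts <- function(series, rate_per_min, magnitude_bpm = 15,
                                   seed = NULL) {
  stopifnot(rate_per_min >= 0)
  if (magnitude_bpm < 10) {
    rlang::warn("spike magnitude below 10 beats/min: the default filter will not remove these")
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(series)
  if (rate_per_min == 0 || n < 3L) {
    return(list(series = series, positions = integer()))
  }
  duration_min <- (max(series$timestamp) - min(series$timestamp)) / 60
  n_spikes <- stats::rpois(1, rate_per_min * duration_min)
  candidates <- sample(2:(n - 1L))
  chosen <- integer()
  for (i in candidates) {
    if (length(chosen) >= n_spikes) break
    if (!any(abs(chosen - i) <= 2L)) chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  signs <- sample(c(-1, 1), length(chosen), replace = TRUE)
  series$hr[chosen] <- series$hr[chosen] + signs * magnitude_bpm
  list(series = series, positions = chosen)
}

#' Simulate epoch-level differences directly from the agreement model
#'
#' Bypasses the device streams and draws paired-epoch differences straight
#' from `d_it = mu + b_i + e_it` with `b_i ~ N(0, tau2)` and `e_it` AR(1)
#' with marginal variance `sigma2`. Used for fast parameter-recovery and
#' coverage studies at the scale of a full study.
#'
#' @param n_participants,epochs_per_participant Study dimensions.
#' @param mu,tau2,sigma2,phi Model parameters (`phi = 0` for independent
#'   residuals).
#' @param hr_level Constant criterion heart rate stamped on the rows (so
#'   the table is a valid paired-epoch table). Default 100.
#' @param seed Optional integer seed.
#' @return A paired-epoch tibble with `participant_id`, `epoch_start`,
#'   `hr_index`, `hr_criterion`, `difference`.
#' @export
simulate_epoch_differences <- function(n_participants, epochs_per_participant,
                                       mu = -0.03, tau2 = 0.61, sigma2 = 26.73,
                                       phi = 0, hr_level = 100, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  m <- epochs_per_participant
  b <- stats::rnorm(n_participants, 0, sqrt(tau2))
  ids <- sprintf("P%03d", seq_len(n_participants))
  rows <- purrr::map2(ids, b, function(id, bi) {
    if (phi == 0) {
      e <- stats::rnorm(m, 0, sqrt(sigma2))
    } else {
      z <- numeric(m)
      z[1] <- stats::rnorm(1)
      innov <- stats::rnorm(m - 1, 0, sqrt(1 - phi^2))
      for (t in seq_len(m - 1)) z[t + 1] <- phi * z[t] + innov[t]
      e <- sqrt(sigma2) * z
    }
    d <- mu + bi + e
    tibble::tibble(participant_id = id,
                   epoch_start = (seq_len(m) - 1) * 5,
                   hr_index = hr_level + d,
                   hr_criterion = hr_level,
                   difference = d)
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic validation study
#'
#' Draws participant ages and bias offsets, simulates every participant's
#' protocol trajectory and paired device recordings, injects criterion
#' spike artefacts, and applies epoch-level index dropouts. With `dir`
#' set, writes `participants.csv`, `index_hr.csv`, `criterion_hr.csv`, and
#' a `manifest.json` recording the seed and all true parameters.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list: `participants`, `index`, `criterion`
#'   (tibbles), `spike_positions` (per participant), and `manifest`.
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_participants
  ages <- truncated_normal(n, config$age_mean, config$age_sd, 18, 65)
  ids <- sprintf("P%02d", seq_len(n))
  b <- stats::rnorm(n, 0, sqrt(config$tau2))
  participants <- tibble::tibble(participant_id = ids, age = round(ages, 1))

  index_all <- vector("list", n)
  criterion_all <- vector("list", n)
  spike_positions <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- simulate_protocol_hr(participants$age[i], config)
    pair <- simulate_device_pair(traj, ids[i], b[i], config)
    spiked <- inject_spike_artifacts(pair$criterion, config$spike_rate_per_min,
                                     config$spike_magnitude_bpm)
    criterion_all[[i]] <- spiked$series
    spike_positions[[i]] <- spiked$positions
    # epoch-level dropouts on the index stream
    idx <- pair$index
    if (config$missing_epoch_prob > 0) {
      epoch_of <- floor(idx$timestamp / config$epoch_s)
      epochs <- unique(epoch_of)
      drop <- epochs[stats::runif(length(epochs)) < config$missing_epoch_prob]
      idx <- idx[!epoch_of %in% drop, ]
    }
    index_all[[i]] <- idx
  }
  index <- dplyr::bind_rows(index_all)
  criterion <- dplyr::bind_rows(criterion_all)
  names(spike_positions) <- ids

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    participant_bias = stats::setNames(as.list(b), ids),
    epoch_variance_shrink_factor = effective_epoch_factor(config),
    epoch_level_sigma2 = if (config$calibrate_epoch_variance) {
      config$sigma2
    } else {
      config$sigma2 * effective_epoch_factor(config)
    }
  )

  out <- list(participants = participants, index = index,
              criterion = criterion, spike_positions = spike_positions,
              manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(participants, file.path(dir, "participants.csv"))
    write_hr_csv(index, file.path(dir, "index_hr.csv"))
    write_hr_csv(criterion, file.path(dir, "criterion_hr.csv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}
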