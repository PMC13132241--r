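# Stream conditioning: R-R to heart rate, spike-artefact removal, clock
# offsets, aggregation onto an absolute 5-s epoch grid, and cross-device
# pairing by shared epoch membership.

#' Convert R-R intervals to instantaneous heart rate
#'
#' One heart-rate sample per beat: hr = 60000 / rr_ms, timestamp carried
#' over from the beat.
#'
#' @param series Tibble with `participant_id`, `timestamp`, `rr_ms`.
#' @return A heart-rate tibble (`participant_id`, `timestamp`, `hr`).
#' @examples
#' rr_to_hr(tibble::tibble(participant_id = "P1", timestamp = 0, rr_ms = 1000))
#' @export
rr_to_hr <- function(series) {
  if (any(series$rr_ms <= 0)) {
    rlang::abort("rr_ms must be positive", class = "hragree_domain_error")
  }
  series |>
    dplyr::transmute(.data$participant_id, .data$timestamp,
                     hr = 60000 / .data$rr_ms)
}

#' Remove transient spike artefacts
#'
#' A sample is removed when it jumps by at least `jump_threshold` beats/min
#' from its predecessor and the following sample returns to the pre-spike
#' level (within `return_tolerance`). Sustained steps are never removed,
#' nor are the first and last samples of a participant's series. Applied
#' per participant; the removal count is reported.
#'
#' @param series Heart-rate tibble, time-sorted within participant.
#' @param jump_threshold Minimum jump, beats/min. Default 10.
#' @param return_tolerance How close the next sample must be to the
#'   pre-spike level to count as a return to baseline, beats/min. Default 5.
#' @return The series with spike samples removed.
#' @export
remove_spike_artifacts <- function(series, jump_threshold = 10, return_tolerance = 5) {
  out <- series |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ {
      keep <- !spike_flags(.x$hr, jump_threshold, return_tolerance)
      .x[keep, ]
    }) |>
    dplyr::ungroup()
  n_removed <- nrow(series) - nrow(out)
  if (n_removed > 0) {
    rlang::inform(sprintf("remove_spike_artifacts: removed %d spike sample(s)", n_removed))
  }
  out
}

# TRUE at positions classified as isolated spikes; endpoints never flagged
spike_flags <- function(hr, jump_threshold, return_tolerance) {
  n <- length(hr)
  if (n < 3L) {
    rlang::warn("series shorter than 3 samples: spike filter not applied")
    return(rep(FALSE, n))
  }
  i <- 2:(n - 1L)
  flag <- rep(FALSE, n)
  flag[i] <- abs(hr[i] - hr[i - 1L]) >= jump_threshold &
    abs(hr[i + 1L] - hr[i - 1L]) <= return_tolerance
  flag
}

#' Shift a series' clock
#'
#' Adds `offset_s` seconds to every timestamp; heart-rate values untouched.
#'
#' @param series Heart-rate tibble.
#' @param offset_s Finite offset in seconds (positive shifts later).
#' @return The shifted series.
#' @export
apply_clock_offset <- function(series, offset_s) {
  if (!is.finite(offset_s)) rlang::abort("offset_s must be finite", class = "hragree_domain_error")
  dplyr::mutate(series, timestamp = .data$timestamp + offset_s)
}

#' Aggregate samples into non-overlapping epochs
#'
#' Windows are half-open intervals `[k*epoch_s, (k+1)*epoch_s)` anchored at
#' absolute multiples of the epoch length (so the grids of two devices
#' coincide without negotiation). The epoch heart rate is the arithmetic
#' mean of all samples falling in the window; empty windows emit no row.
#'
#' @param series Heart-rate tibble, time-sorted and artefact-filtered.
#' @param epoch_s Epoch length in seconds. Default 5.
#' @return A tibble `participant_id`, `epoch_start`, `hr_mean`, `n_samples`.
#' @export
epoch_aggregate <- function(series, epoch_s = 5) {
  if (epoch_s <= 0) rlang::abort("epoch_s must be positive", class = "hragree_domain_error")
  series |>
    dplyr::mutate(epoch_start = floor(.data$timestamp / epoch_s) * epoch_s) |>
    dplyr::group_by(.data$participant_id, .data$epoch_start) |>
    dplyr::summarise(hr_mean = mean(.data$hr), n_samples = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$epoch_start)
}

#' Pair epoched streams across devices
#'
#' Keeps the epochs present in *both* streams for a participant (an inner
#' join on the shared absolute grid, realising nearest-neighbour matching
#' within each window). Epochs covered by only one device are excluded.
#' The difference is defined as index minus criterion.
#'
#' @param index Epoched series for the index (wearable) device.
#' @param criterion Epoched series for the criterion (reference) device.
#' @return A paired-epoch tibble `participant_id`, `epoch_start`,
#'   `hr_index`, `hr_criterion`, `difference`.
#' @export
pair_epochs <- function(index, criterion) {
  if (nrow(index) > 0 && nrow(criterion) > 0 &&
      !any(unique(index$participant_id) %in% unique(criterion$participant_id))) {
    rlang::abort("no participant appears in both streams: check participant_id values",
                 class = "hragree_pairing_error")
  }
  paired <- dplyr::inner_join(
    dplyr::select(index, "participant_id", "epoch_start", hr_index = "hr_mean"),
    dplyr::select(criterion, "participant_id", "epoch_start", hr_criterion = "hr_mean"),
    by = c("participant_id", "epoch_start")
  )
  paired |>
    dplyr::mutate(difference = .data$hr_index - .data$hr_criterion) |>
    dplyr::arrange(.data$participant_id, .data$epoch_start)
}
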