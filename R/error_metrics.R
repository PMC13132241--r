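# Exercise-intensity zones (% of age-predicted HRmax) and absolute error
# summaries: MAE / MAPE / signed error, participant-averaged or pooled,
# overall or stratified by zone.

.ZONE_LEVELS <- c("rest", "light", "moderate", "vigorous")

#' Age-predicted maximal heart rate
#'
#' `HRmax = 220 - age` (beats/min).
#'
#' @param age Age in years; must satisfy `0 <= age < 220`.
#' @return Predicted HRmax, vectorised over `age`.
#' @examples
#' predicted_hrmax(20) # 200
#' @export
predicted_hrmax <- function(age) {
  if (any(!is.finite(age) | age < 0 | age >= 220)) {
    rlang::abort("age must be finite, >= 0 and < 220", class = "hragree_domain_error")
  }
  220 - age
}

#' Classify heart rate into an exercise-intensity zone
#'
#' Zones on the %HRmax scale, half-open so every real-valued percentage
#' falls in exactly one zone: rest `< 40%`, light `[40, 60)%`, moderate
#' `[60, 75)%`, vigorous `>= 75%`.
#'
#' @param hr_criterion Criterion (reference) heart rate, beats/min.
#' @param hrmax Maximal heart rate, beats/min; both must be positive.
#' @return A factor with levels `rest < light < moderate < vigorous`.
#' @examples
#' classify_zone(c(78, 80, 150), hrmax = 200)
#' @export
classify_zone <- function(hr_criterion, hrmax) {
  if (any(hr_criterion <= 0) || any(hrmax <= 0)) {
    rlang::abort("heart rates and hrmax must be positive", class = "hragree_domain_error")
  }
  pct <- 100 * hr_criterion / hrmax
  cut(pct, breaks = c(-Inf, 40, 60, 75, Inf), labels = .ZONE_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Attach intensity zones to a paired-epoch table
#'
#' Zone assignment uses the criterion (chest-strap) epoch heart rate
#' against each participant's age-predicted HRmax.
#'
#' @param table Paired-epoch tibble.
#' @param participants Tibble with `participant_id`, `age`; every
#'   participant in `table` must appear.
#' @return `table` with a `zone` factor column.
#' @export
add_zones <- function(table, participants) {
  missing <- setdiff(unique(table$participant_id), participants$participant_id)
  if (length(missing)) {
    rlang::abort(sprintf("no age on record for participant(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "hragree_lookup_error")
  }
  table |>
    dplyr::left_join(dplyr::select(participants, "participant_id", "age"),
                     by = "participant_id") |>
    dplyr::mutate(zone = classify_zone(.data$hr_criterion, predicted_hrmax(.data$age))) |>
    dplyr::select(-"age")
}

#' Absolute error summaries for paired epochs
#'
#' Per epoch, the absolute error is `|difference|` and the absolute
#' percentage error `100 * |difference| / hr_criterion`. Two weightings:
#' `"participant_averaged"` computes each metric per participant first and
#' then takes the unweighted mean across participants (so participants with
#' more epochs do not dominate); `"pooled"` averages over all epochs. The
#' signed mean error is reported alongside.
#'
#' @param table Paired-epoch tibble; needs a `zone` column when
#'   `by_zone = TRUE` (see [add_zones()]).
#' @param weighting `"participant_averaged"` or `"pooled"`.
#' @param by_zone Stratify by intensity zone? Default `FALSE`.
#' @return A tibble with `n_epochs`, `mean_signed_error`, `mae`,
#'   `mape_percent` (and `zone` when `by_zone`), plus a `weighting` column.
#' @export
error_summary <- function(table, weighting = c("participant_averaged", "pooled"),
                          by_zone = FALSE) {
  weighting <- match.arg(weighting)
  if (nrow(table) == 0L) rlang::abort("empty paired-epoch table", class = "hragree_empty_input")
  if (any(table$hr_criterion == 0)) {
    rlang::abort("hr_criterion of 0 makes MAPE undefined", class = "hragree_domain_error")
  }
  if (by_zone && !"zone" %in% names(table)) {
    rlang::abort("by_zone = TRUE requires a zone column (see add_zones)",
                 class = "hragree_domain_error")
  }
  strata <- if (by_zone) "zone" else character()
  per_epoch <- dplyr::mutate(table,
                             abs_err = abs(.data$difference),
                             ape = 100 * abs(.data$difference) / .data$hr_criterion)
  out <- if (weighting == "pooled") {
    per_epoch |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
      dplyr::summarise(n_epochs = dplyr::n(),
                       mean_signed_error = mean(.data$difference),
                       mae = mean(.data$abs_err),
                       mape_percent = mean(.data$ape),
                       .groups = "drop")
  } else {
    per_epoch |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(strata, "participant_id")))) |>
      dplyr::summarise(n_epochs = dplyr::n(),
                       mean_signed_error = mean(.data$difference),
                       mae = mean(.data$abs_err),
                       mape_percent = mean(.data$ape),
                       .groups = "drop_last") |>
      dplyr::summarise(n_epochs = sum(.data$n_epochs),
                       mean_signed_error = mean(.data$mean_signed_error),
                       mae = mean(.data$mae),
                       mape_percent = mean(.data$mape_percent),
                       .groups = "drop")
  }
  dplyr::mutate(out, weighting = weighting)
}

#' Zone-stratified agreement summary table
#'
#' Per intensity zone: pooled epoch count, mean heart rate of each device,
#' mean bias (index minus criterion), SD of the differences, and MAE/MAPE
#' under the requested weighting. Zones with no epochs are omitted. Rows
#' are ordered rest to vigorous.
#'
#' @param table Paired-epoch tibble (zones added here if absent).
#' @param participants Tibble with `participant_id`, `age`.
#' @param weighting Passed to [error_summary()]. Default
#'   `"participant_averaged"`.
#' @return A tibble with one row per populated zone: `zone`, `n_epochs`,
#'   `mean_hr_index`, `mean_hr_criterion`, `mean_bias`, `sd_of_differences`,
#'   `mae`, `mape_percent`, `weighting`.
#' @export
zone_summary <- function(table, participants,
                         weighting = c("participant_averaged", "pooled")) {
  weighting <- match.arg(weighting)
  if (!"zone" %in% names(table)) table <- add_zones(table, participants)
  base <- table |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(n_epochs = dplyr::n(),
                     mean_hr_index = mean(.data$hr_index),
                     mean_hr_criterion = mean(.data$hr_criterion),
                     mean_bias = mean(.data$difference),
                     sd_of_differences = stats::sd(.data$difference),
                     .groups = "drop")
  err <- error_summary(table, weighting = weighting, by_zone = TRUE) |>
    dplyr::select("zone", "mae", "mape_percent", "weighting")
  base |>
    dplyr::inner_join(err, by = "zone") |>
    dplyr::arrange(.data$zone)
}
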