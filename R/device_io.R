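# Neutral CSV schemas for device streams, participants, and paired epochs.
# All readers return tibbles sorted by time within participant; rows that
# fail physiological plausibility bounds are dropped with a message.

# plausibility bounds applied at read time
.HR_BOUNDS <- c(25, 250)   # beats/min
.RR_BOUNDS <- c(200, 3000) # ms

#' Read a heart-rate stream CSV
#'
#' Reads a per-device heart-rate export in the neutral schema
#' `participant_id,timestamp,hr` (timestamp in seconds UTC, ISO-8601 also
#' accepted; hr in beats/min). Rows with non-finite hr or hr outside the
#' plausible range (25, 250) beats/min are dropped and the count reported.
#'
#' @param path Path to a CSV file with header `participant_id,timestamp,hr`.
#' @param device_role `"index"` (the wearable under validation) or
#'   `"criterion"` (the reference device).
#' @return A tibble with columns `participant_id`, `timestamp` (numeric
#'   seconds), `hr`, `device_role`, sorted by timestamp within participant.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant_id,timestamp,hr", "P1,0,70", "P1,1,71"), f)
#' read_hr_csv(f, "criterion")
#' @export
read_hr_csv <- function(path, device_role = c("index", "criterion")) {
  device_role <- match.arg(device_role)
  df <- read_stream_csv(path, value_col = "hr")
  bad <- !is.finite(df$hr) | df$hr <= .HR_BOUNDS[1] | df$hr >= .HR_BOUNDS[2]
  if (any(bad)) {
    rlang::inform(sprintf("read_hr_csv: dropped %d row(s) with implausible or non-finite hr", sum(bad)))
    df <- df[!bad, ]
  }
  if (nrow(df) == 0L) rlang::abort("no valid heart-rate rows after filtering", class = "hragree_empty_input")
  df |>
    dplyr::mutate(device_role = device_role) |>
    dplyr::arrange(.data$participant_id, .data$timestamp) |>
    tibble::as_tibble()
}

#' Read an R-R interval stream CSV
#'
#' Schema `participant_id,timestamp,rr_ms`. Intervals outside (200, 3000) ms
#' (i.e. outside 20-300 beats/min) are dropped with a reported count.
#'
#' @param path Path to a CSV file with header `participant_id,timestamp,rr_ms`.
#' @return A tibble `participant_id`, `timestamp`, `rr_ms`, time-sorted
#'   within participant.
#' @export
read_rr_csv <- function(path) {
  df <- read_stream_csv(path, value_col = "rr_ms")
  bad <- !is.finite(df$rr_ms) | df$rr_ms <= .RR_BOUNDS[1] | df$rr_ms >= .RR_BOUNDS[2]
  if (any(bad)) {
    rlang::inform(sprintf("read_rr_csv: dropped %d row(s) with implausible rr_ms", sum(bad)))
    df <- df[!bad, ]
  }
  if (nrow(df) == 0L) rlang::abort("no valid R-R rows after filtering", class = "hragree_empty_input")
  dplyr::arrange(df, .data$participant_id, .data$timestamp)
}

#' Read a participant table CSV
#'
#' Schema `participant_id,age` (age in years). Ages must leave a positive
#' age-predicted maximal heart rate under 220 - age.
#'
#' @param path Path to a CSV file with header `participant_id,age`.
#' @return A tibble `participant_id`, `age`.
#' @export
read_participants_csv <- function(path) {
  check_file(path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("participant_id", "age"), path)
  df <- dplyr::mutate(df, participant_id = as.character(.data$participant_id),
                      age = as.numeric(.data$age))
  if (any(!is.finite(df$age) | df$age < 0 | df$age >= 220)) {
    rlang::abort("participant ages must be finite, >= 0 and < 220", class = "hragree_domain_error")
  }
  tibble::as_tibble(df)
}

# shared stream reader: schema checks, timestamp parsing, row-level errors
read_stream_csv <- function(path, value_col) {
  check_file(path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) {
    rlang::abort(sprintf("empty input file: %s", path), class = "hragree_empty_input")
  }
  check_columns(df, c("participant_id", "timestamp", value_col), path)
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts)) {
    bad_line <- which(is.na(ts))[1] + 1L # + header
    rlang::abort(sprintf("unparseable timestamp at line %d of %s", bad_line, path),
                 class = "hragree_parse_error")
  }
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    timestamp = ts,
    !!value_col := suppressWarnings(as.numeric(df[[value_col]]))
  )
}

# fractional seconds since epoch; ISO-8601 strings converted on read
parse_timestamp <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  iso <- is.na(num) & !is.na(x)
  if (any(iso)) {
    parse_one <- function(s) {
      tryCatch(as.numeric(as.POSIXct(s, tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                    "%Y-%m-%d %H:%M:%OS"))),
               error = function(e) NA_real_)
    }
    batch <- tryCatch(
      as.numeric(as.POSIXct(x[iso], tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS"))),
      error = function(e) vapply(x[iso], parse_one, 0, USE.NAMES = FALSE))
    num[iso] <- batch
  }
  num
}

check_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "hragree_io_error")
  }
}

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("file %s is missing required column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 class = "hragree_schema_error")
  }
}

#' Write a heart-rate stream CSV
#' @param series Tibble with `participant_id`, `timestamp`, `hr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(series, path) {
  readr::write_csv(series[, c("participant_id", "timestamp", "hr")], path)
  invisible(path)
}

#' Write an R-R interval stream CSV
#' @param series Tibble with `participant_id`, `timestamp`, `rr_ms`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  readr::write_csv(series[, c("participant_id", "timestamp", "rr_ms")], path)
  invisible(path)
}

#' Write a paired-epoch table CSV
#'
#' Column order is fixed as
#' `participant_id,epoch_start,hr_index,hr_criterion,difference,zone`;
#' the `zone` column is written empty when zones have not been assigned.
#'
#' @param table A paired-epoch tibble from [pair_epochs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_epochs <- function(table, path) {
  if (nrow(table) == 0L) rlang::abort("paired-epoch table is empty", class = "hragree_empty_input")
  if (!"zone" %in% names(table)) table$zone <- NA_character_
  out <- table[, c("participant_id", "epoch_start", "hr_index", "hr_criterion",
                   "difference", "zone")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a paired-epoch table CSV
#' @param path Path written by [write_paired_epochs()].
#' @return A paired-epoch tibble.
#' @export
read_paired_epochs <- function(path) {
  check_file(path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(participant_id = readr::col_character(),
                                                zone = readr::col_character()))
  check_columns(df, c("participant_id", "epoch_start", "hr_index",
                      "hr_criterion", "difference", "zone"), path)
  tibble::as_tibble(df)
}
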