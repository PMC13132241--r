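# in-code fixtures shared across test files

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# small paired-epoch table built by hand
toy_paired <- function() {
  tibble::tibble(
    participant_id = rep(c("A", "B"), each = 3),
    epoch_start = rep(c(0, 5, 10), 2),
    hr_index = c(101, 103, 102, 125, 127, 126),
    hr_criterion = c(100, 100, 100, 120, 120, 120)
  ) |>
    dplyr::mutate(difference = hr_index - hr_criterion)
}

# paired table from per-participant difference vectors (criterion fixed)
paired_from_diffs <- function(diffs, hr_criterion = 100) {
  dplyr::bind_rows(purrr::imap(diffs, function(d, id) {
    tibble::tibble(participant_id = id,
                   epoch_start = (seq_along(d) - 1) * 5,
                   hr_index = hr_criterion + d,
                   hr_criterion = hr_criterion,
                   difference = d)
  }))
}
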