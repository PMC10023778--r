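#' Weekly presence and detection rates
#'
#' Aggregates detections into ISO-8601 weekly bins. The Presence Rate (PR)
#' of a week is the fraction of that week's recordings containing at least
#' one qualifying detection; the Detection Rate (DR) is the number of
#' qualifying calls divided by the minutes recorded that week. A detection
#' qualifies if it is a 20 Hz note, or a 130 Hz note in a recording with no
#' 20 Hz detection (the high-frequency note emitted alone). Weeks inside
#' the deployment span with no recordings are emitted with `pr`/`dr`
#' missing, not zero; weeks with recordings but no detections get
#' `pr = dr = 0`.
#'
#' @param detections Tibble with `recording_id`, `note_class_guess` (or
#'   `note_class`).
#' @param sessions Tibble with `recording_id`, `start_time` (POSIXct),
#'   `duration_min`. A recording belongs to the ISO week of its start.
#' @return Tibble of weekly bins: `iso_year`, `iso_week`, `week_start`
#'   (Monday), `n_recordings`, `n_with_detection`, `n_calls`,
#'   `minutes_recorded`, `pr`, `dr`.
#' @export
weekly_rates <- function(detections, sessions) {
  cls <- detections[["note_class_guess"]] %||% detections[["note_class"]]
  if (nrow(detections) > 0 && is.null(cls)) {
    abort("detections need a note_class_guess or note_class column")
  }
  unknown <- setdiff(detections$recording_id, sessions$recording_id)
  if (length(unknown) > 0) {
    abort(paste0("detections reference unknown sessions: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  det <- detections |> mutate(note_class = cls)
  per_rec <- det |>
    summarise(has_lf = any(.data$note_class == "LF20"),
              n_lf = sum(.data$note_class == "LF20"),
              n_hf = sum(.data$note_class == "HF130"),
              .by = "recording_id") |>
    mutate(n_qualifying = ifelse(.data$has_lf, .data$n_lf, .data$n_hf),
           with_detection = .data$n_qualifying > 0)

  weekly <- sessions |>
    left_join(per_rec, by = "recording_id") |>
    mutate(iso_year = lubridate::isoyear(.data$start_time),
           iso_week = lubridate::isoweek(.data$start_time)) |>
    summarise(
      n_recordings = n(),
      n_with_detection = sum(.data$with_detection, na.rm = TRUE),
      n_calls = sum(.data$n_qualifying, na.rm = TRUE),
      minutes_recorded = sum(.data$duration_min),
      .by = c("iso_year", "iso_week")
    )

  # full ISO-week grid across the deployment span; empty weeks are missing
  wk_start <- lubridate::floor_date(min(sessions$start_time), "week",
                                    week_start = 1)
  wk_end <- lubridate::floor_date(max(sessions$start_time), "week",
                                  week_start = 1)
  grid <- tibble(week_start = seq(wk_start, wk_end, by = "7 days")) |>
    mutate(iso_year = lubridate::isoyear(.data$week_start),
           iso_week = lubridate::isoweek(.data$week_start))

  grid |>
    left_join(weekly, by = c("iso_year", "iso_week")) |>
    mutate(
      n_recordings = ifelse(is.na(.data$n_recordings), 0L, .data$n_recordings),
      pr = ifelse(.data$n_recordings > 0,
                  .data$n_with_detection / .data$n_recordings, NA_real_),
      dr = ifelse(.data$n_recordings > 0,
                  .data$n_calls / .data$minutes_recorded, NA_real_)
    ) |>
    select("iso_year", "iso_week", "week_start", "n_recordings",
           "n_with_detection", "n_calls", "minutes_recorded", "pr", "dr")
}

#' Attach weekly sea-surface temperature to rate bins
#'
#' Weekly mean and SD over the days available in each ISO week; weeks with
#' no SST days keep the bin with missing temperature (no interpolation).
#'
#' @param bins Weekly bins from [weekly_rates()].
#' @param sst Daily series tibble with `date`, `sst_c`.
#' @return `bins` with `sst_mean_c` and `sst_sd_c` columns.
#' @export
attach_sst <- function(bins, sst) {
  wk <- sst |>
    filter(!is.na(.data$sst_c)) |>
    mutate(iso_year = lubridate::isoyear(.data$date),
           iso_week = lubridate::isoweek(.data$date)) |>
    summarise(sst_mean_c = mean(.data$sst_c),
              sst_sd_c = sd(.data$sst_c),
              n_sst_days = n(),
              .by = c("iso_year", "iso_week"))
  bins |> left_join(wk, by = c("iso_year", "iso_week"))
}
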