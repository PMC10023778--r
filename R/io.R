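fmt_utc <- function(t) strftime(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

parse_utc <- function(x, what, line_offset = 0) {
  has_tz <- grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  if (any(!has_tz & !is.na(x))) {
    abort(paste0(what, ": timestamps must carry an explicit timezone ",
                 "(lines ",
                 paste(head(which(!has_tz) + line_offset, 5), collapse = ", "),
                 ")"))
  }
  lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
}

check_cols <- function(df, needed, what) {
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing columns: ", paste(miss, collapse = ", ")))
  }
}

#' Read and write ground-truth annotations
#'
#' Fixed CSV dialect: UTF-8, header row, ISO-8601 UTC timestamps, `.`
#' decimal. Columns: `recording_id`, `onset_s`, `abs_time`, `note_class`,
#' `song_id`, `in_audio`, `is_rest_flank`. Rows with unparseable
#' timestamps or timestamps lacking a timezone are rejected with their
#' line numbers.
#'
#' @param notes Annotations tibble (the `notes` element of an
#'   [synth_deployment()] result).
#' @param path CSV path.
#' @return `read_annotations()` returns the annotations tibble;
#'   writers return `path` invisibly.
#' @export
write_annotations <- function(notes, path) {
  notes |>
    mutate(abs_time = fmt_utc(.data$abs_time)) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          recording_id = "c", onset_s = "d", abs_time = "c",
                          note_class = "c", song_id = "c",
                          in_audio = "l", is_rest_flank = "l"))
  check_cols(df, c("recording_id", "onset_s", "abs_time", "note_class",
                   "song_id", "in_audio"), "annotations CSV")
  at <- parse_utc(df$abs_time, "annotations CSV", line_offset = 1)
  bad <- which(is.na(at) & !is.na(df$abs_time))
  if (length(bad) > 0) {
    abort(paste0("annotations CSV: malformed timestamps at lines ",
                 paste(head(bad + 1, 5), collapse = ", ")))
  }
  df |> mutate(abs_time = at)
}

#' Read and write detections
#'
#' Columns: `recording_id`, `onset_s`, `duration_s`, `peak_score`,
#' `note_class_guess`, `abs_time`.
#'
#' @param detections Detections tibble (see [detect_deployment()]).
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  detections |>
    mutate(abs_time = fmt_utc(.data$abs_time)) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          recording_id = "c", onset_s = "d", duration_s = "d",
                          peak_score = "d", note_class_guess = "c",
                          abs_time = "c"))
  check_cols(df, c("recording_id", "onset_s", "note_class_guess"),
             "detections CSV")
  df |> mutate(abs_time = parse_utc(.data$abs_time, "detections CSV",
                                    line_offset = 1))
}

#' Read and write a daily SST series
#'
#' Columns `date` (ISO dates) and `sst_c`. Missing days stay as gaps; the
#' reader never interpolates.
#'
#' @param sst Tibble with `date`, `sst_c`.
#' @param path CSV path.
#' @export
write_sst <- function(sst, path) {
  readr::write_csv(sst, path)
  invisible(path)
}

#' @rdname write_sst
#' @export
read_sst <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(date = "D", sst_c = "d"))
  check_cols(df, c("date", "sst_c"), "SST CSV")
  bad <- which(is.na(df$date))
  if (length(bad) > 0) {
    abort(paste0("SST CSV: malformed dates at lines ",
                 paste(head(bad + 1, 5), collapse = ", ")))
  }
  df
}

#' Read a pipeline configuration (YAML)
#'
#' A single document fully determines a run. Top-level keys: `deployment`
#' (start, end, sample_rate, duty_on_min, songs, noise), `detector`,
#' `spectrogram`, `songstruct`, `stats`, `seed`. Unknown keys anywhere at
#' the top level are rejected.
#'
#' @param path YAML file.
#' @return A validated config list (class `fs_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A config list built in code.
#' @export
validate_pipeline_config <- function(cfg) {
  allowed <- c("deployment", "detector", "spectrogram", "songstruct",
               "stats", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) abort("config requires a seed")
  if (is.null(cfg$deployment)) abort("config requires a deployment block")
  dep <- cfg$deployment
  dep_allowed <- c("start", "end", "sample_rate", "duty_on_min", "songs",
                   "noise")
  unknown <- setdiff(names(dep), dep_allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown deployment keys: ", paste(unknown, collapse = ", ")))
  }
  start <- parse_utc(dep$start, "deployment start")
  end <- parse_utc(dep$end, "deployment end")
  if (is.na(start) || is.na(end)) abort("deployment start/end unparseable")
  if (end <= start) abort("deployment end must be after start")
  structure(cfg, class = "fs_config")
}

config_to_deployment <- function(cfg) {
  dep <- cfg$deployment
  noise <- do.call(noise_spec, as.list(dep$noise %||% list()))
  songs <- map(dep$songs %||% list(), function(s) {
    im <- ini_model(
      kind = s$kind %||% "unimodal",
      mean_s = s$mean_s, mode_short_s = s$mode_short_s,
      mode_long_s = s$mode_long_s, sd_s = s$sd_s %||% 0,
      rest_mean_s = s$rest_mean_s %||% 25, rest_sd_s = s$rest_sd_s %||% 2
    )
    song_spec(
      im, n_notes = s$n_notes %||% 21,
      note_template = note_spec(s$note_class %||% "LF20",
                                level_db = s$level_db %||% 30),
      with_hf130 = isTRUE(s$with_hf130),
      hf130_only = isTRUE(s$hf130_only),
      n_rests = s$n_rests %||% 0,
      start_time = parse_utc(s$start_time, "song start_time")
    )
  })
  deployment_spec(
    start = parse_utc(dep$start, "deployment start"),
    end = parse_utc(dep$end, "deployment end"),
    songs = songs, seed = cfg$seed,
    sample_rate = dep$sample_rate %||% 500,
    duty_on_min = dep$duty_on_min %||% 30,
    noise = noise
  )
}
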