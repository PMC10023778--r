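recording_id_for <- function(hour_start) {
  strftime(hour_start, "%Y%m%dT%H%M%SZ", tz = "UTC")
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

band_limited_click <- function(n, band, sample_rate, peak) {
  if (n < 16) n <- 16L
  x <- rnorm(n)
  w <- pmin(band / (sample_rate / 2), 0.99)
  bf <- signal::butter(4, w, type = "pass")
  y <- signal::filtfilt(bf, x) * tukey_window(n, 0.5)
  peak * y / max(abs(y))
}

#' Synthesize a duty-cycled deployment with ground truth
#'
#' Builds the full recording schedule (the first `duty_on_min` minutes of
#' every hour between `start` and `end`), realizes every song, places notes
#' into recordings, and synthesizes per-recording audio: Gaussian ambient
#' noise, Poisson broadband transients, and the song notes. Notes falling in
#' off-duty minutes are dropped from the audio but kept in the ground truth
#' with `in_audio = FALSE`. Runs are bit-reproducible under the spec's seed.
#'
#' @param spec A [deployment_spec()].
#' @param out_dir Directory for the WAV files (one per recording, named by
#'   the recording's start timestamp, ISO-8601 basic, UTC). `NULL` skips
#'   audio synthesis entirely and returns ground truth only.
#' @param skip_empty If `TRUE`, recordings containing no notes are scheduled
#'   and listed but no WAV is written for them (the audio would be pure
#'   noise); their `file` is `NA`. Keeps long sparse deployments cheap.
#' @return A list of class `fs_deployment`: `recordings` (tibble:
#'   `recording_id`, `file`, `start_time`, `sample_rate`, `duration_min`),
#'   `notes` (tibble: `recording_id`, `onset_s` within recording,
#'   `abs_time`, `note_class`, `song_id`, `in_audio`, `is_rest_flank`),
#'   `songs` (list of realized songs, each carrying its `inis` and `rests`).
#' @export
synth_deployment <- function(spec, out_dir = NULL, skip_empty = FALSE) {
  stopifnot(inherits(spec, "deployment_spec"))
  fs <- spec$sample_rate
  on_s <- spec$duty_on_min * 60

  first_hour <- lubridate::ceiling_date(spec$start, "hour", change_on_boundary = FALSE)
  hours <- seq(first_hour, spec$end, by = "hour")
  hours <- hours[hours < spec$end]
  if (length(hours) == 0) abort("deployment window contains no recording start")
  rec_minutes <- pmin(spec$duty_on_min,
                      as.numeric(difftime(spec$end, hours, units = "mins")))
  recordings <- tibble(
    recording_id = recording_id_for(hours),
    file = NA_character_,
    start_time = hours,
    sample_rate = fs,
    duration_min = rec_minutes
  )

  with_preserved_rng(spec$seed, {
    songs <- list()
    notes_all <- list()
    for (i in seq_along(spec$songs)) {
      ss <- spec$songs[[i]]
      rs <- realize_song(ss)
      rs$spec <- ss
      rs$song_id <- sprintf("song%03d", i)
      rs$start_time <- ss$start_time
      abs_time <- ss$start_time + rs$notes$onset_s
      if (max(abs_time) < spec$start || min(abs_time) > spec$end) {
        warn(sprintf("song %d lies entirely outside the deployment; skipped", i))
        next
      }
      songs[[rs$song_id]] <- rs
      hour0 <- lubridate::floor_date(abs_time, "hour")
      within_s <- as.numeric(difftime(abs_time, hour0, units = "secs"))
      rid <- recording_id_for(hour0)
      known <- rid %in% recordings$recording_id
      in_audio <- known & within_s < on_s
      notes_all[[rs$song_id]] <- tibble(
        recording_id = ifelse(in_audio, rid, NA_character_),
        onset_s = ifelse(in_audio, within_s, NA_real_),
        abs_time = abs_time,
        note_class = rs$notes$note_class,
        song_id = rs$song_id,
        in_audio = in_audio,
        is_rest_flank = rs$notes$is_rest_flank
      )
    }
    notes <- if (length(notes_all)) list_rbind(notes_all) else
      tibble(recording_id = character(), onset_s = numeric(),
             abs_time = as.POSIXct(character(), tz = "UTC"),
             note_class = character(), song_id = character(),
             in_audio = logical(), is_rest_flank = logical())

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      amb <- 10^(spec$noise$ambient_level_db / 20)
      for (r in seq_len(nrow(recordings))) {
        rid <- recordings$recording_id[r]
        idx <- which(notes$in_audio & notes$recording_id == rid)
        if (skip_empty && length(idx) == 0) next
        n <- round(recordings$duration_min[r] * 60 * fs)
        x <- rnorm(n, 0, amb)
        n_tr <- stats::rpois(1, spec$noise$transient_rate *
                                  recordings$duration_min[r] / 60)
        if (n_tr > 0) {
          t_on <- sort(runif(n_tr, 0, recordings$duration_min[r] * 60))
          peak <- amb * 10^(spec$noise$transient_level_db / 20)
          for (tt in t_on) {
            click <- band_limited_click(round(spec$noise$transient_duration_s * fs),
                                        spec$noise$transient_band, fs, peak)
            i0 <- round(tt * fs) + 1
            span <- i0:min(n, i0 + length(click) - 1)
            x[span] <- x[span] + click[seq_along(span)]
          }
        }
        for (k in idx) {
          nspec <- note_template_for(songs[[notes$song_id[k]]]$spec,
                                     notes$note_class[k])
          wave <- synth_note(nspec, fs, ambient_sd = amb)
          i0 <- round(notes$onset_s[k] * fs) + 1
          span <- i0:min(n, i0 + length(wave) - 1)
          x[span] <- x[span] + wave[seq_along(span)]
        }
        path <- file.path(out_dir, paste0(rid, ".wav"))
        wav_write(pmin(1, pmax(-1, x)), path, fs)
        recordings$file[r] <- path
      }
    }

    structure(list(recordings = recordings, notes = notes, songs = songs,
                   spec = spec),
              class = "fs_deployment")
  })
}

note_template_for <- function(song_spec, note_class) {
  tpl <- song_spec$note_template
  if (identical(tpl$note_class, note_class)) return(tpl)
  if (note_class == "HF130") return(note_spec("HF130", level_db = tpl$level_db))
  tpl
}

#' @export
print.fs_deployment <- function(x, ...) {
  cat("<fs_deployment> ", nrow(x$recordings), " recordings, ",
      nrow(x$notes), " notes (", sum(x$notes$in_audio), " in audio), ",
      length(x$songs), " songs\n", sep = "")
  invisible(x)
}
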