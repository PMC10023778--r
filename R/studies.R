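#' Reference song parameters per singing season
#'
#' The season-by-season inter-note-interval catalogue for fin whale song
#' at the Svalbard monitoring site that this package's synthetic
#' deployments emulate: per season and note class, the unimodal INI mean
#' and SD, and (for the 2014/15 doublet pattern) the two alternating mode
#' locations. These are the generator's ground-truth defaults and the
#' recovery targets for pipeline validation.
#'
#' @return A tibble with `season`, `note_class`, `pattern`, `mean_s`,
#'   `sd_s`, `mode_short_s`, `mode_long_s`.
#' @examples
#' svalbard_song_params()
#' @export
svalbard_song_params <- function() {
  tibble::tribble(
    ~season,   ~note_class, ~pattern,   ~mean_s, ~sd_s, ~mode_short_s, ~mode_long_s,
    "2014/15", "LF20",      "bimodal",    11.92,  2.40,             9,           14,
    "2014/15", "LF20",      "unimodal",   14.66,  0.99,            NA,           NA,
    "2014/15", "HF130",     "bimodal",    10.51,  2.35,            NA,           NA,
    "2014/15", "HF130",     "unimodal",   15.42,  0.29,            NA,           NA,
    "2015/16", "LF20",      "unimodal",   15.08,  2.30,            NA,           NA,
    "2015/16", "HF130",     "unimodal",   15.13,  0.42,            NA,           NA,
    "2016/17", "LF20",      "unimodal",   10.17,  1.34,            NA,           NA,
    "2018/19", "LF20",      "unimodal",   10.31,  0.54,            NA,           NA,
    "2018/19", "HF130",     "unimodal",   10.35,  0.65,            NA,           NA,
    "2019/20", "LF20",      "unimodal",   10.81,  0.41,            NA,           NA,
    "2019/20", "HF130",     "unimodal",   10.57,  0.63,            NA,           NA
  )
}

#' @rdname svalbard_song_params
#' @return `rest_duration_params()`: a tibble with `group`, `mean_s`,
#'   `sd_s` — rest durations are shorter (about 18 s) in songs with short
#'   (~9 s) INIs and longer (about 32 s) with long (15-16 s) INIs.
#' @export
rest_duration_params <- function() {
  tibble::tribble(
    ~group,      ~mean_s, ~sd_s,
    "SHORT_INI",   17.73,  1.00,
    "LONG_INI",    32.50,  2.63
  )
}

#' Recover a grand mean INI through the full audio pipeline
#'
#' Generates `n_songs` synthetic songs (one per day, so every song clears
#' the 24 h independence filter), synthesizes duty-cycled audio at the
#' requested SNR, runs band-energy detection, segments the detected note
#' stream into songs, applies the INI selection filters, and returns the
#' grand mean of all selected INIs. This is the package's end-to-end
#' parameter-recovery harness.
#'
#' @param mean_s,sd_s Unimodal INI mean and SD, seconds.
#' @param note_class `"LF20"` or `"HF130"`; the matching detector band is
#'   used.
#' @param n_songs,n_notes Songs generated and notes per song.
#' @param seed Integer seed.
#' @param level_db Note level above the ambient floor, dB.
#' @param start First song's day, Date.
#' @param out_dir Scratch directory for the WAV files (a fresh temporary
#'   directory by default, deleted on exit).
#' @return List: `grand_mean_s`, `n_inis`, `n_songs_selected`,
#'   `detections`, `songs`.
#' @export
recover_ini_mean <- function(mean_s, sd_s, note_class = "LF20",
                             n_songs = 20, n_notes = 21, seed = 1,
                             level_db = 30,
                             start = as.Date("2015-10-01"),
                             out_dir = NULL) {
  cleanup <- is.null(out_dir)
  if (cleanup) {
    out_dir <- tempfile("ini_recovery_")
    on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  }
  im <- ini_model("unimodal", mean_s = mean_s, sd_s = sd_s)
  day0 <- as.POSIXct(paste(start, "00:02:00"), tz = "UTC")
  songs <- map(seq_len(n_songs), function(k) {
    song_spec(im, n_notes = n_notes,
              note_template = note_spec(note_class, level_db = level_db),
              hf130_only = note_class == "HF130",
              start_time = day0 + (k - 1) * 86400)
  })
  spec <- deployment_spec(
    start = day0 - 120, end = day0 + n_songs * 86400,
    songs = songs, seed = seed
  )
  dep <- synth_deployment(spec, out_dir = out_dir, skip_empty = TRUE)
  cfg <- if (note_class == "HF130") hf130_config() else detector_config()
  dets <- detect_deployment(dep$recordings, configs = list(cfg))
  seg <- segment_songs(dets |> rename(note_class = "note_class_guess"),
                       note_class = note_class)
  sel <- select_song_inis(seg)
  inis <- unlist(sel$selected_inis)
  list(grand_mean_s = mean(inis), n_inis = length(inis),
       n_songs_selected = nrow(sel), detections = dets, songs = sel)
}

#' Simulate a season of songs from ground-truth note times
#'
#' Realizes each requested song (no audio), places songs one day apart,
#' and returns the combined note table plus the per-song generator truth.
#' Used for song-structure analyses where the quantity under study is the
#' segmentation/selection/classification layer rather than the detector.
#'
#' @param song_defs Tibble with one row per song: `kind` ("unimodal" or
#'   "bimodal_doublet"), `mean_s`, `sd_s`, `mode_short_s`, `mode_long_s`,
#'   `n_notes`, `n_rests`, `rest_mean_s`, `rest_sd_s`, `note_class`.
#'   Missing columns fall back to defaults.
#' @param seed Integer seed.
#' @param start First song's day, Date.
#' @return List: `notes` (tibble `abs_time`, `note_class`), `truth` (list
#'   of realized songs).
#' @export
simulate_song_season <- function(song_defs, seed = 1,
                                 start = as.Date("2014-10-01")) {
  day0 <- as.POSIXct(paste(start, "00:02:00"), tz = "UTC")
  with_preserved_rng(seed, {
    notes <- list()
    truth <- list()
    fld <- function(d, nm, def) {
      v <- if (nm %in% names(d)) d[[nm]] else NA
      if (length(v) == 1 && !is.na(v)) v else def
    }
    for (i in seq_len(nrow(song_defs))) {
      d <- song_defs[i, ]
      im <- ini_model(
        kind = fld(d, "kind", "unimodal"),
        mean_s = fld(d, "mean_s", NULL),
        mode_short_s = fld(d, "mode_short_s", NULL),
        mode_long_s = fld(d, "mode_long_s", NULL),
        sd_s = fld(d, "sd_s", 0),
        rest_mean_s = fld(d, "rest_mean_s", 25),
        rest_sd_s = fld(d, "rest_sd_s", 2)
      )
      cls <- fld(d, "note_class", "LF20")
      sp <- song_spec(im, n_notes = fld(d, "n_notes", 21),
                      note_template = note_spec(cls),
                      hf130_only = cls == "HF130",
                      n_rests = fld(d, "n_rests", 0),
                      start_time = day0 + (i - 1) * 86400)
      rs <- realize_song(sp)
      truth[[i]] <- rs
      notes[[i]] <- tibble(abs_time = sp$start_time + rs$notes$onset_s,
                           note_class = rs$notes$note_class)
    }
    list(notes = list_rbind(notes), truth = truth)
  })
}
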