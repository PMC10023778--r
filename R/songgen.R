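#' Specify a single song note
#'
#' A note is a windowed frequency sweep. The three classes follow the
#' stereotyped fin whale song components: `"LF20"` is the classic 20 Hz
#' downsweep (25 to 15 Hz over 0.5-1 s), `"HF130"` the higher upsweep note
#' centred near 130 Hz, and `"BACKBEAT"` a near-constant 18-20 Hz note of
#' about 0.8 s.
#'
#' @param note_class One of `"LF20"`, `"HF130"`, `"BACKBEAT"`.
#' @param f_start,f_end Start and end instantaneous frequency, Hz.
#' @param duration Note duration, seconds.
#' @param level_db Peak level in dB above the ambient noise floor.
#' @return A `note_spec` list.
#' @examples
#' note_spec("LF20")
#' note_spec("HF130", f_start = 125, f_end = 135, duration = 0.5)
#' @export
note_spec <- function(note_class = c("LF20", "HF130", "BACKBEAT"),
                      f_start = NULL, f_end = NULL,
                      duration = NULL, level_db = 30) {
  note_class <- match.arg(note_class)
  defaults <- switch(note_class,
    LF20     = list(f_start = 25, f_end = 15, duration = 1.0),
    HF130    = list(f_start = 125, f_end = 135, duration = 0.5),
    BACKBEAT = list(f_start = 19, f_end = 19, duration = 0.8)
  )
  f_start  <- f_start %||% defaults$f_start
  f_end    <- f_end %||% defaults$f_end
  duration <- duration %||% defaults$duration
  stopifnot(duration > 0, is.finite(level_db))
  if (note_class == "LF20") {
    if (!(f_start >= f_end && f_start <= 25 && f_end >= 15)) {
      abort("LF20 must be a downsweep within [15, 25] Hz")
    }
    if (duration < 0.5 || duration > 1.0) {
      abort("LF20 duration must lie in [0.5, 1] s")
    }
  }
  if (note_class == "BACKBEAT" &&
      !(f_start >= 18 && f_start <= 20 && f_end >= 18 && f_end <= 20)) {
    abort("BACKBEAT frequency must lie in [18, 20] Hz")
  }
  if (note_class == "HF130" && !(f_start <= f_end)) {
    abort("HF130 must be an upsweep (f_start <= f_end)")
  }
  structure(list(note_class = note_class, f_start = f_start, f_end = f_end,
                 duration = duration, level_db = level_db),
            class = "note_spec")
}

#' Specify an inter-note-interval (INI) distribution
#'
#' Unimodal songs draw every INI from one Gaussian; bimodal doublet songs
#' alternate between a short and a long mode (the alternation is exact
#' before jitter). Jitter is Gaussian, truncated at plus/minus 3 SD and at
#' zero, so printed mean/SD pairs are honoured without negative intervals.
#' Rest durations, used when a song contains rests, are drawn the same way
#' from `rest_mean_s`/`rest_sd_s`.
#'
#' @param kind `"unimodal"` or `"bimodal_doublet"`.
#' @param mean_s Unimodal INI mean, seconds.
#' @param mode_short_s,mode_long_s Doublet mode locations, seconds.
#' @param sd_s INI jitter SD, seconds (0 switches jitter off).
#' @param rest_mean_s,rest_sd_s Rest-duration distribution, seconds.
#' @return An `ini_model` list.
#' @examples
#' ini_model("unimodal", mean_s = 15.08, sd_s = 2.30)
#' ini_model("bimodal_doublet", mode_short_s = 9, mode_long_s = 14, sd_s = 0.3)
#' @export
ini_model <- function(kind = c("unimodal", "bimodal_doublet"),
                      mean_s = NULL, mode_short_s = NULL, mode_long_s = NULL,
                      sd_s = 0, rest_mean_s = 25, rest_sd_s = 2) {
  kind <- match.arg(kind)
  stopifnot(sd_s >= 0, rest_mean_s > 0, rest_sd_s >= 0)
  if (kind == "unimodal") {
    if (is.null(mean_s) || mean_s <= 0) abort("unimodal model needs mean_s > 0")
  } else {
    if (is.null(mode_short_s) || is.null(mode_long_s)) {
      abort("doublet model needs mode_short_s and mode_long_s")
    }
    if (!(mode_short_s > 0 && mode_short_s < mode_long_s)) {
      abort("doublet modes must satisfy 0 < mode_short_s < mode_long_s")
    }
  }
  structure(list(kind = kind, mean_s = mean_s, mode_short_s = mode_short_s,
                 mode_long_s = mode_long_s, sd_s = sd_s,
                 rest_mean_s = rest_mean_s, rest_sd_s = rest_sd_s),
            class = "ini_model")
}

#' Specify one song within a deployment
#'
#' @param ini_model An [ini_model()].
#' @param n_notes Number of notes (>= 2).
#' @param note_template A [note_spec()] for the song's primary class.
#' @param with_hf130 If `TRUE`, each 20 Hz note is paired with a 130 Hz note
#'   at a fixed 1 s offset, so both classes share the same INI sequence.
#' @param hf130_only If `TRUE`, the song consists exclusively of 130 Hz notes.
#' @param n_rests Number of within-song rests (silent gaps replacing an
#'   inter-note interval).
#' @param start_time Song start, POSIXct (UTC).
#' @return A `song_spec` list.
#' @export
song_spec <- function(ini_model, n_notes, note_template = note_spec("LF20"),
                      with_hf130 = FALSE, hf130_only = FALSE, n_rests = 0,
                      start_time = as.POSIXct("2014-10-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(ini_model, "ini_model"), n_notes >= 2, n_rests >= 0)
  if (hf130_only) note_template <- note_spec("HF130")
  if (n_rests > 0 && n_rests > ceiling((n_notes - 3) / 2)) {
    abort("too many rests: every sequence needs at least 2 notes")
  }
  structure(list(ini_model = ini_model, n_notes = as.integer(n_notes),
                 note_template = note_template, with_hf130 = with_hf130,
                 hf130_only = hf130_only, n_rests = as.integer(n_rests),
                 start_time = lubridate::with_tz(start_time, "UTC")),
            class = "song_spec")
}

#' Specify the noise environment
#'
#' Ambient noise is Gaussian and white at the synthesis rate;
#' transients are short broadband impulses band-limited to emulate ice
#' cracking and anthropogenic sources, arriving as a Poisson process.
#'
#' @param ambient_level_db Ambient noise floor, dB re full scale (the SD of
#'   the Gaussian ambient samples is `10^(ambient_level_db / 20)`).
#' @param transient_rate Transient events per hour.
#' @param transient_band Two-element Hz band of the transients.
#' @param transient_duration_s Transient duration, seconds.
#' @param transient_level_db Transient peak level, dB above ambient.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(ambient_level_db = -40, transient_rate = 0,
                       transient_band = c(10, 100),
                       transient_duration_s = 0.3,
                       transient_level_db = 25) {
  stopifnot(transient_rate >= 0, length(transient_band) == 2,
            transient_band[1] < transient_band[2], transient_duration_s > 0)
  structure(list(ambient_level_db = ambient_level_db,
                 transient_rate = transient_rate,
                 transient_band = transient_band,
                 transient_duration_s = transient_duration_s,
                 transient_level_db = transient_level_db),
            class = "noise_spec")
}

#' Specify a duty-cycled deployment
#'
#' @param start,end Deployment window, POSIXct (UTC); `end > start`.
#' @param sample_rate Synthesis rate, Hz (default 500, the analysis rate).
#' @param duty_on_min Minutes recorded at the top of each hour, in (0, 60].
#' @param songs List of [song_spec()] objects.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; required so deployments are reproducible.
#' @return A `deployment_spec` list.
#' @export
deployment_spec <- function(start, end, songs, seed,
                            sample_rate = 500, duty_on_min = 30,
                            noise = noise_spec()) {
  start <- lubridate::with_tz(start, "UTC")
  end <- lubridate::with_tz(end, "UTC")
  stopifnot(end > start, duty_on_min > 0, duty_on_min <= 60,
            sample_rate >= 500, inherits(noise, "noise_spec"))
  if (missing(seed) || is.null(seed)) abort("deployment_spec requires a seed")
  if (inherits(songs, "song_spec")) songs <- list(songs)
  stopifnot(all(vapply(songs, inherits, logical(1), "song_spec")))
  structure(list(start = start, end = end, sample_rate = sample_rate,
                 duty_on_min = duty_on_min, songs = songs, noise = noise,
                 seed = as.integer(seed)),
            class = "deployment_spec")
}

# Truncated-normal draws: Gaussian truncated at +/- 3 SD and at > 0.
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- rnorm(length(need), mean, sd)
    ok <- x > 0 & abs(x - mean) <= 3 * sd
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

#' Synthesize one note as a windowed linear chirp
#'
#' The instantaneous frequency moves linearly from `spec$f_start` to
#' `spec$f_end` over the note duration, under a Tukey (tapered cosine)
#' window. Peak amplitude is `ambient_sd * 10^(spec$level_db / 20)`, i.e.
#' `level_db` is read relative to the ambient floor.
#'
#' @param spec A [note_spec()].
#' @param sample_rate Sampling rate, Hz; must be at least twice the highest
#'   frequency in the sweep.
#' @param ambient_sd Reference ambient noise SD in full-scale units.
#' @return Numeric waveform of `round(duration * sample_rate)` samples.
#' @examples
#' w <- synth_note(note_spec("LF20"), 500)
#' length(w)  # 500 samples for a 1 s note at 500 Hz
#' @export
synth_note <- function(spec, sample_rate, ambient_sd = 0.01) {
  stopifnot(inherits(spec, "note_spec"))
  f_max <- max(spec$f_start, spec$f_end)
  if (sample_rate < 2 * f_max) {
    abort(sprintf(
      "sample_rate %g Hz violates the Nyquist bound: need >= %g Hz for a %g Hz note",
      sample_rate, 2 * f_max, f_max))
  }
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  sweep_rate <- (spec$f_end - spec$f_start) / spec$duration
  phase <- 2 * pi * (spec$f_start * t + 0.5 * sweep_rate * t^2)
  amp <- ambient_sd * 10^(spec$level_db / 20)
  amp * tukey_window(n) * sin(phase)
}

#' Realize a song: draw its note times, INIs and rests
#'
#' INIs are drawn from the song's [ini_model()] (alternating short/long for
#' doublets); at each of `n_rests` interior interval positions the interval
#' is replaced by a rest drawn from the model's rest distribution, so the
#' onset gap at a rest equals the rest duration. Ground-truth INIs never
#' include a rest-spanning interval. When `with_hf130` is set each 20 Hz
#' note is paired with a 130 Hz note 1 s later, so both classes carry the
#' same INI sequence.
#'
#' @param spec A [song_spec()].
#' @return A list with `notes` (tibble: `onset_s`, `note_class`,
#'   `is_rest_flank`), `inis` (numeric, rest-spanning intervals excluded),
#'   `rests` (tibble: `after_note`, `start_s`, `duration_s`).
#' @examples
#' sp <- song_spec(ini_model("unimodal", mean_s = 15.08, sd_s = 0), n_notes = 11)
#' realize_song(sp)$inis  # ten intervals of exactly 15.08 s
#' @export
realize_song <- function(spec) {
  stopifnot(inherits(spec, "song_spec"))
  if (spec$n_notes < 2) abort("a song needs at least 2 notes")
  m <- spec$ini_model
  n_int <- spec$n_notes - 1L

  gaps <- if (m$kind == "unimodal") {
    rtruncnorm3(n_int, m$mean_s, m$sd_s)
  } else {
    modes <- rep(c(m$mode_short_s, m$mode_long_s), length.out = n_int)
    vapply(modes, function(mu) rtruncnorm3(1, mu, m$sd_s), numeric(1))
  }

  rest_at <- integer(0)
  if (spec$n_rests > 0) {
    # interior intervals only, never adjacent, so every sequence keeps >= 2 notes
    candidates <- seq(2L, n_int - 1L)
    repeat {
      rest_at <- sort(candidates[sample.int(length(candidates), spec$n_rests)])
      if (spec$n_rests == 1 || min(diff(rest_at)) > 1) break
    }
    gaps[rest_at] <- rtruncnorm3(spec$n_rests, m$rest_mean_s, m$rest_sd_s)
  }

  onsets <- c(0, cumsum(gaps))
  is_rest_gap <- seq_len(n_int) %in% rest_at
  cls <- if (spec$hf130_only) "HF130" else spec$note_template$note_class
  notes <- tibble(
    onset_s = onsets,
    note_class = cls,
    is_rest_flank = c(is_rest_gap, FALSE) | c(FALSE, is_rest_gap)
  )
  if (isTRUE(spec$with_hf130) && !spec$hf130_only) {
    hf <- notes |> mutate(onset_s = .data$onset_s + 1.0, note_class = "HF130")
    notes <- bind_rows(notes, hf) |> arrange(.data$onset_s)
  }
  rests <- tibble(after_note = rest_at,
                  start_s = onsets[rest_at],
                  duration_s = gaps[rest_at])
  list(notes = notes, inis = gaps[!is_rest_gap], rests = rests)
}

#' Synthesize a daily sea-surface-temperature series
#'
#' An annual sinusoid (baseline 3.2 degC, amplitude 1.7 degC, maximum in late
#' July) plus Gaussian day-to-day noise, calibrated so monthly means sit
#' inside the Svalbard coastal envelopes this pipeline assumes: roughly
#' 1-4 degC October-May and 4-8 degC June-September. Optional cold-anomaly
#' weeks pull the series to 0 degC and an ice-covered episode holds it below
#' -2 degC.
#'
#' @param start,end Dates (inclusive).
#' @param noise_sd Day-to-day noise SD, degC.
#' @param cold_weeks Optional vector of Dates: weeks (starting at each date)
#'   pulled down to about 0 degC.
#' @param ice_episode Optional length-2 Date vector: period held at -2 degC
#'   or below.
#' @return Tibble with `date` and `sst_c`.
#' @examples
#' sst <- synth_sst(as.Date("2015-01-01"), as.Date("2015-12-31"), noise_sd = 0)
#' mean(sst$sst_c[lubridate::month(sst$date) == 7])
#' @export
synth_sst <- function(start, end, noise_sd = 0.4,
                      cold_weeks = NULL, ice_episode = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) abort("end must be after start")
  dates <- seq(start, end, by = "day")
  doy <- as.numeric(strftime(dates, "%j"))
  base <- 3.2 + 1.7 * cos(2 * pi * (doy - 205) / 365.25)
  sst <- base + rnorm(length(dates), 0, noise_sd)
  for (cw in as.list(cold_weeks)) {
    idx <- dates >= as.Date(cw) & dates < as.Date(cw) + 7
    sst[idx] <- pmin(sst[idx], rnorm(sum(idx), 0, 0.2))
  }
  if (!is.null(ice_episode)) {
    idx <- dates >= as.Date(ice_episode[1]) & dates <= as.Date(ice_episode[2])
    sst[idx] <- -2 - abs(rnorm(sum(idx), 0.3, 0.2))
  }
  tibble(date = dates, sst_c = sst)
}
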