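test_that("synthesized notes have the right length and spectral content", {
  w <- synth_note(note_spec("LF20", f_start = 25, f_end = 15, duration = 1), 500)
  expect_length(w, 500)

  # degenerate sweep: constant-frequency tone
  tone <- synth_note(note_spec("LF20", f_start = 20, f_end = 20,
                               duration = 1), 500)
  expect_equal(fft_peak_hz(tone, 500), 20, tolerance = 0.5)

  # HF upsweep: dominant FFT bin within the sweep band
  hf <- synth_note(note_spec("HF130", f_start = 125, f_end = 135,
                             duration = 0.5), 500)
  pk <- fft_peak_hz(hf, 500)
  expect_gte(pk, 125)
  expect_lte(pk, 135)

  # spectrogram ridge of the default downsweep stays inside [15, 25] Hz
  pad <- c(numeric(1000), synth_note(note_spec("LF20"), 500), numeric(1000))
  sp <- stft_power(pad, 500)
  ridge <- sp$freq[apply(sp$power, 2, which.max)]
  loud <- colSums(sp$power) > 0.5 * max(colSums(sp$power))
  expect_true(all(ridge[loud] >= 15 & ridge[loud] <= 25))
})

test_that("note synthesis rejects sampling below Nyquist", {
  expect_error(synth_note(note_spec("HF130"), 200), "Nyquist")
})

test_that("note spec invariants are enforced", {
  expect_error(note_spec("LF20", f_start = 15, f_end = 25), "downsweep")
  expect_error(note_spec("LF20", duration = 2), "duration")
  expect_error(note_spec("BACKBEAT", f_start = 25), "18")
})

test_that("jitter-free songs realize their INI model exactly", {
  sp <- song_spec(ini_model("unimodal", mean_s = 15.08, sd_s = 0),
                  n_notes = 11)
  rs <- realize_song(sp)
  expect_equal(rs$inis, rep(15.08, 10))
  # oracle: INIs are exactly the onset differences
  expect_equal(rs$inis, diff(rs$notes$onset_s))

  doublet <- song_spec(ini_model("bimodal_doublet", mode_short_s = 9,
                                 mode_long_s = 14, sd_s = 0), n_notes = 5)
  expect_equal(realize_song(doublet)$inis, c(9, 14, 9, 14))
})

test_that("rests replace an interval and are excluded from ground-truth INIs", {
  set.seed(4)
  sp <- song_spec(ini_model("unimodal", mean_s = 10, sd_s = 0,
                            rest_mean_s = 30, rest_sd_s = 0),
                  n_notes = 12, n_rests = 1)
  rs <- realize_song(sp)
  expect_equal(nrow(rs$rests), 1)
  expect_equal(rs$rests$duration_s, 30)
  expect_length(rs$inis, 10)           # 11 intervals minus the rest
  expect_true(all(rs$inis == 10))
  # the onset gap at the rest position equals the drawn rest duration
  gaps <- diff(rs$notes$onset_s)
  expect_equal(sort(unique(gaps)), c(10, 30))
  expect_equal(sum(rs$notes$is_rest_flank), 2)
})

test_that("paired 130 Hz notes share the 20 Hz INI sequence", {
  set.seed(9)
  sp <- song_spec(ini_model("unimodal", mean_s = 12, sd_s = 0.5),
                  n_notes = 11, with_hf130 = TRUE)
  rs <- realize_song(sp)
  lf <- rs$notes$onset_s[rs$notes$note_class == "LF20"]
  hf <- rs$notes$onset_s[rs$notes$note_class == "HF130"]
  expect_equal(diff(hf), diff(lf))
  expect_equal(hf - lf, rep(1.0, length(lf)))
})

test_that("songs need at least 2 notes", {
  expect_error(song_spec(ini_model("unimodal", mean_s = 10), n_notes = 1))
})

test_that("realized INI sample mean approaches the model mean", {
  set.seed(123)
  m <- ini_model("unimodal", mean_s = 10.31, sd_s = 0.54)
  draws <- unlist(purrr::map(1:60, function(i) {
    realize_song(song_spec(m, n_notes = 21))$inis
  }))
  expect_gt(length(draws), 1000)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 10.31), 3 * se + 1e-9)
})

test_that("duty-cycled schedule produces one recording per on-window", {
  dep <- synth_deployment(tiny_deployment(), out_dir = NULL)
  expect_equal(nrow(dep$recordings), 2)
  expect_equal(dep$recordings$duration_min, c(30, 30))
  expect_equal(dep$recordings$start_time,
               utc(c("2015-10-01 00:00:00", "2015-10-01 01:00:00")))
})

test_that("notes after minute 30 drop from audio but stay in ground truth", {
  im <- ini_model("unimodal", mean_s = 60, sd_s = 0)
  s <- song_spec(im, n_notes = 10, start_time = utc("2015-10-01 00:25:00"))
  spec <- deployment_spec(utc("2015-10-01 00:00:00"),
                          utc("2015-10-01 02:00:00"), list(s), seed = 2)
  dep <- synth_deployment(spec)
  # notes at minutes 25..34 of hour 0: minutes 25-29 on duty, 30-34 off
  expect_equal(sum(dep$notes$in_audio), 5)
  expect_equal(nrow(dep$notes), 10)
  # conservation: ground truth = in-audio + off-duty
  expect_equal(nrow(dep$notes),
               sum(dep$notes$in_audio) + sum(!dep$notes$in_audio))
})

test_that("a song scheduled outside the deployment is skipped with a warning", {
  im <- ini_model("unimodal", mean_s = 10, sd_s = 0)
  s <- song_spec(im, n_notes = 5, start_time = utc("2020-01-01 00:00:00"))
  spec <- deployment_spec(utc("2015-10-01 00:00:00"),
                          utc("2015-10-01 02:00:00"), list(s), seed = 2)
  expect_warning(dep <- synth_deployment(spec), "outside")
  expect_equal(nrow(dep$notes), 0)
})

test_that("seeded deployments are byte-identical", {
  d1 <- file.path(tempdir(), "repro1"); d2 <- file.path(tempdir(), "repro2")
  spec <- tiny_deployment(seed = 77, transient_rate = 4)
  synth_deployment(spec, out_dir = d1)
  synth_deployment(spec, out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("synthetic SST respects the seasonal envelopes", {
  set.seed(5)
  july <- purrr::map_dbl(1:100, function(i) {
    s <- synth_sst(as.Date("2015-07-01"), as.Date("2015-07-31"))
    mean(s$sst_c)
  })
  expect_true(all(july >= 4 & july <= 8))
  jan <- purrr::map_dbl(1:100, function(i) {
    s <- synth_sst(as.Date("2015-01-01"), as.Date("2015-01-31"))
    mean(s$sst_c)
  })
  expect_true(all(jan >= 1 & jan <= 4))
})

test_that("noise-free SST is a deterministic sinusoid", {
  a <- synth_sst(as.Date("2015-01-01"), as.Date("2015-12-31"), noise_sd = 0)
  b <- synth_sst(as.Date("2015-01-01"), as.Date("2015-12-31"), noise_sd = 0)
  expect_identical(a, b)
  ice <- synth_sst(as.Date("2019-11-01"), as.Date("2020-02-28"),
                   ice_episode = as.Date(c("2019-12-10", "2020-01-20")))
  idx <- ice$date >= as.Date("2019-12-10") & ice$date <= as.Date("2020-01-20")
  expect_true(all(ice$sst_c[idx] <= -2))
})

test_that("WAV files round-trip mono 16-bit PCM", {
  f <- tempfile(fileext = ".wav")
  x <- sin(2 * pi * 20 * seq(0, 2, by = 1 / 500)) * 0.4
  wav_write(x, f, 500)
  w <- wav_read(f)
  expect_equal(w$sample_rate, 500)
  expect_equal(length(w$samples), length(x))
  expect_equal(w$samples, x, tolerance = 1e-4)
  expect_warning(wav_write(c(0, 2, -2), f, 500), "clipped")
  unlink(f)
})
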