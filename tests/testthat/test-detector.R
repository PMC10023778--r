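test_that("downsampling preserves duration and in-band tones", {
  set.seed(1)
  x <- rnorm(48000 * 60)
  y <- downsample(x, 48000, 500)
  expect_lte(abs(length(y) - 30000), 1)

  # oracle: FFT amplitude of a pure tone before and after decimation
  t48 <- seq(0, 60 - 1 / 48000, by = 1 / 48000)
  for (f in c(20, 200)) {
    tone <- sin(2 * pi * f * t48)
    a_in <- tone_amplitude(tone, 48000, f)
    dn <- downsample(tone, 48000, 500)
    a_out <- tone_amplitude(dn[501:(length(dn) - 500)], 500, f)
    expect_lt(abs(20 * log10(a_out / a_in)), 1)   # < 1 dB loss
  }

  expect_identical(downsample(x[1:100], 500, 500), x[1:100])
  expect_error(downsample(x, 500, 1000), "exceeds")
})

test_that("white-noise band energies match the flat-spectrum bandwidth ratio", {
  # oracle: for flat-PSD noise, mean in-band energy is proportional to
  # band width, so E[18-25] / E[25-100] ~ 7/75 (signal band excluded
  # from the ratio band)
  cfg <- detector_config()
  ratios <- purrr::map_dbl(1:10, function(s) {
    set.seed(s)
    sp <- stft_power(rnorm(100 * 500, 0, 0.01), 500)
    sc <- band_energy_score(sp, cfg)
    mean(sc$sig_energy) / mean(sc$ratio_energy)
  })
  expect_equal(mean(ratios), 7 / 75, tolerance = 0.08)
  # and the equalized score never crosses the shipped threshold on noise
  for (s in 1:10) {
    set.seed(s)
    sc <- band_energy_score(stft_power(rnorm(100 * 500, 0, 0.01), 500), cfg)
    expect_lt(max(sc$score), cfg$threshold)
  }
})

test_that("a clean note produces a supra-threshold run over its support", {
  set.seed(2)
  fs <- 500
  x <- rnorm(60 * fs, 0, 0.01)
  w <- synth_note(note_spec("LF20"), fs, 0.01)
  x[15001:(15000 + length(w))] <- x[15001:(15000 + length(w))] + w  # at 30 s
  cfg <- detector_config()
  sp <- stft_power(x, fs)
  sc <- band_energy_score(sp, cfg)
  hot <- sc$time_s[sc$score > cfg$threshold] + sp$frame_s
  expect_gt(length(hot), 0)
  expect_true(any(hot >= 30 & hot <= 31.5))
  expect_true(all(abs(hot - 30.5) < 3))
})

test_that("silent audio scores at the floor with zero detections", {
  cfg <- detector_config()
  sp <- stft_power(numeric(30 * 500), 500)
  sc <- band_energy_score(sp, cfg)
  expect_true(all(sc$floored))
  expect_true(all(sc$score == 0))
  expect_equal(nrow(gate_detections(sc, cfg, sp$frame_s)), 0)
})

test_that("duration and neighbourhood gates behave as configured", {
  cfg <- detector_config(threshold = 5, smoothing_frames = 1)
  hop <- 0.256
  mk_scores <- function(hot_frames, n = 200) {
    tibble::tibble(frame = 1:n, time_s = (0:(n - 1)) * hop,
                   score = ifelse(1:n %in% hot_frames, 10, 0),
                   sig_energy = ifelse(1:n %in% hot_frames, 1, 1e-6),
                   ratio_energy = 1, floored = FALSE)
  }
  # two 3-frame runs 1.0 s apart (4 frames gap) merge into one detection
  d <- gate_detections(mk_scores(c(20:22, 27:29)), cfg, 2.048)
  expect_equal(nrow(d), 1)
  # 3.0 s run (12 frames) exceeds the 2.5 s max duration: discarded
  expect_equal(nrow(gate_detections(mk_scores(50:61), cfg, 2.048)), 0)
  # runs 3 s apart (beyond the 2.5 s neighbourhood) stay separate
  d2 <- gate_detections(mk_scores(c(20:22, 35:37)), cfg, 2.048)
  expect_equal(nrow(d2), 2)
})

test_that("the band-ratio score is invariant to waveform scaling", {
  set.seed(3)
  fs <- 500
  x <- rnorm(30 * fs, 0, 0.01)
  w <- synth_note(note_spec("LF20"), fs, 0.01)
  x[4001:(4000 + length(w))] <- x[4001:(4000 + length(w))] + w
  cfg <- detector_config()
  s1 <- band_energy_score(stft_power(x, fs), cfg)$score
  s2 <- band_energy_score(stft_power(x * 37.5, fs), cfg)$score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("raising the threshold never increases the detection count", {
  set.seed(4)
  fs <- 500
  x <- rnorm(120 * fs, 0, 0.01)
  for (o in seq(10, 110, by = 11)) {
    w <- synth_note(note_spec("LF20", level_db = 15), fs, 0.01)
    i0 <- round(o * fs) + 1
    x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
  }
  sp <- stft_power(x, fs)
  counts <- purrr::map_int(c(2, 4, 6, 10, 20, 50), function(th) {
    cfg <- detector_config(threshold = th)
    nrow(gate_detections(band_energy_score(sp, cfg), cfg, sp$frame_s))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("detected onsets match truth within one hop on clean songs", {
  # every season pattern, jitter-free, noise-free
  pars <- svalbard_song_params()
  pars <- pars[pars$pattern == "unimodal" & pars$note_class == "LF20", ]
  fs <- 500
  hop <- 1024 / 8 / fs
  for (i in seq_len(nrow(pars))) {
    ons <- cumsum(c(5, rep(pars$mean_s[i], 7)))
    x <- numeric(round((max(ons) + 5) * fs))
    for (o in ons) {
      w <- synth_note(note_spec("LF20"), fs, 0.01)
      i0 <- round(o * fs) + 1
      x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
    }
    d <- detect_notes(x, fs)
    expect_equal(nrow(d), length(ons))
    err <- purrr::map_dbl(ons, function(o) min(abs(d$onset_s - o)))
    expect_true(all(err <= hop + 1e-9),
                label = paste("season", pars$season[i]))
  }
})

test_that("sensitivity and FPR hold up on a noisy transient-rich deployment", {
  im <- ini_model("unimodal", mean_s = 10.81, sd_s = 0.41)
  songs <- purrr::map(0:2, function(k) {
    song_spec(im, n_notes = 21, note_template = note_spec("LF20", level_db = 10),
              start_time = utc("2015-10-01 00:02:00") + k * 3600)
  })
  spec <- deployment_spec(utc("2015-10-01 00:00:00"), utc("2015-10-01 03:00:00"),
                          songs, seed = 101,
                          noise = noise_spec(transient_rate = 6))
  out <- file.path(tempdir(), "noisy_dep")
  dep <- synth_deployment(spec, out_dir = out)
  dets <- detect_deployment(dep$recordings)
  sc <- score_detector(dets, dep)
  expect_gte(sc$sensitivity, 0.90)
  expect_lte(sc$false_positive_rate, 0.05)
  unlink(out, recursive = TRUE)
})

test_that("detector scoring matches hand counts on a constructed instance", {
  sessions <- tibble::tibble(recording_id = "r1", duration_min = 100 / 60)
  truth <- tibble::tibble(recording_id = "r1",
                          onset_s = seq(5.5, 95.5, by = 10),  # 10 notes
                          in_audio = TRUE)
  # detect 8 of 10, plus one spurious detection in an empty second
  dets <- tibble::tibble(recording_id = "r1",
                         onset_s = c(seq(5.5, 75.5, by = 10), 50.2))
  s <- score_detector(dets, truth, sessions)
  # hand count: tp 8, fn 2, fp 1; 100 blocks, 10 hold truth onsets,
  # 1 of the remaining 90 holds the spurious detection -> tn 89
  expect_equal(s$tp, 8)
  expect_equal(s$fn, 2)
  expect_equal(s$fp, 1)
  expect_equal(s$tn, 89)
  expect_equal(s$sensitivity, 0.8)
  expect_equal(s$accuracy, (8 + 89) / 100)

  # perfect detector
  perf <- score_detector(truth |> dplyr::mutate(onset_s = onset_s + 0.1),
                         truth, sessions)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$false_positive_rate, 0)

  # null detector
  null <- score_detector(dets[0, ], truth, sessions)
  expect_equal(null$sensitivity, 0)
  expect_equal(null$fn, 10)

  expect_error(score_detector(dets, truth, sessions, match_tol_s = 0),
               "positive")
  expect_error(score_detector(dplyr::mutate(dets, recording_id = "zz"),
                              truth, sessions), "unknown")
})
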