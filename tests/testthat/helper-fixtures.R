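# Shared fixtures: everything is generated in code at test time.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A small deployment: one song in the first half hour of a 2 h window.
tiny_deployment <- function(seed = 11, n_notes = 15, mean_s = 12, sd_s = 0.5,
                            n_rests = 0, transient_rate = 0, level_db = 30) {
  im <- ini_model("unimodal", mean_s = mean_s, sd_s = sd_s,
                  rest_mean_s = 25, rest_sd_s = 1)
  s <- song_spec(im, n_notes, note_template = note_spec("LF20", level_db = level_db),
                 n_rests = n_rests, start_time = utc("2015-10-01 00:02:00"))
  deployment_spec(utc("2015-10-01 00:00:00"), utc("2015-10-01 02:00:00"),
                  list(s), seed = seed,
                  noise = noise_spec(transient_rate = transient_rate))
}

# Dominant STFT frequency of a waveform segment (independent FFT oracle).
fft_peak_hz <- function(x, fs) {
  sp <- abs(stats::fft(x))[seq_len(floor(length(x) / 2))]
  (which.max(sp) - 1) * fs / length(x)
}

# Amplitude of a pure tone via FFT magnitude (oracle for the downsampler).
# The window is trimmed to an integer number of tone cycles so spectral
# leakage does not bias the reading.
tone_amplitude <- function(x, fs, f) {
  n_cycle <- fs / f
  n <- floor(length(x) / n_cycle) * n_cycle
  x <- x[seq_len(n)]
  k <- round(f * n / fs)
  2 * abs(stats::fft(x))[k + 1] / n
}

# All permutations of 1..n, one per column (for exhaustive rank oracles).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(k, sub + (sub >= k))
  }))
}

# Note table at given absolute second offsets from a base time.
note_table <- function(offsets_s, base = utc("2015-10-01 00:00:00"),
                       note_class = "LF20") {
  tibble::tibble(abs_time = base + offsets_s, note_class = note_class)
}
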