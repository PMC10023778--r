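# Example pipeline configuration: a two-hour duty-cycled deployment with
# one unimodal 20 Hz song. A single document fully determines a run.
seed: 42
deployment:
  start: "2015-10-01T00:00:00Z"
  end: "2015-10-01T02:00:00Z"
  sample_rate: 500
  duty_on_min: 30
  noise:
    ambient_level_db: -40
    transient_rate: 6
  songs:
    - kind: unimodal
      mean_s: 15.08
      sd_s: 2.30
      n_notes: 21
      n_rests: 1
      rest_mean_s: 32.5
      rest_sd_s: 2.63
      start_time: "2015-10-01T00:02:00Z"
detector:
  threshold: 6
spectrogram:
  frame_size: 1024
  hop_fraction: 0.125
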