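# Demo configuration: synthesizes a small neuron-GB coculture recording and
# runs the full analysis. Output goes to a temporary directory unless
# out_dir is set.
seed: 1
frame_interval: 0.5
calibration: 1.0
synthesize:
  n_neurons: 6
  n_gb: 4
  height: 160
  width: 160
  n_frames: 240
  noise_sd: 0
detection:
  activity_threshold: 180
  median_radius: 5
  min_area: 50
  max_area: 200
trace:
  smooth_window: 10
  prominence_min: 0.07
area:
  threshold: otsu
  min_size: 50
stats:
  enabled: true
  features: [width_s, freq_hz]
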