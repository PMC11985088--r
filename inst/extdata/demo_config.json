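{
  "panel": "default",
  "protocol": {
    "voltages": [100, 80, 60, 40, 20, -140],
    "per_voltage_duration": 10
  },
  "acquisition": {
    "fs": 5000,
    "filter_cutoff": 1000,
    "filter_order": 4,
    "noise_sd": 0.25,
    "oversample_factor": 10
  },
  "fit": { "v_lo": 0, "v_hi": 100 },
  "growth": { "timepoint": 48, "feature": "activity_meas" },
  "seed": 1
}
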