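{
  "name": "wt",
  "description": "Wild-type control. Terminal-type parameters encode the ordinal structure clearance Ib > Is > II and per-AP influx II > Is > Ib, so detection-threshold frequencies order II < Is < Ib (10/20/40 Hz).",
  "placeholder_note": "Resting Ca2+ and per-AP influx increments at these terminals are not quantified in the literature this model draws on; ca_rest and delta_ca_per_ap are illustrative placeholders calibrated only to reproduce ordinal frequency-response relations and half-decay magnitudes (~0.5 s type I, ~0.8 s type II).",
  "indicator": "GCaMP1.3",
  "noise_sigma_dff": 0.02,
  "frame_rate": 25,
  "pump_scale": 1.0,
  "types": {
    "Ib": {
      "ca_rest": 50, "delta_ca_per_ap": 0.29, "k_leak": 0.3,
      "pump_vmax": 180, "pump_km": 150,
      "aps_per_stimulus": 1, "burst_rate": 100, "refractory_period": 0.002,
      "failure_recovery_time": 0, "rebound_rate": 0, "rebound_duration": 0,
      "rebound_delay": 0
    },
    "Is": {
      "ca_rest": 50, "delta_ca_per_ap": 0.53, "k_leak": 0.3,
      "pump_vmax": 157.5, "pump_km": 150,
      "aps_per_stimulus": 1, "burst_rate": 100, "refractory_period": 0.002,
      "failure_recovery_time": 0, "rebound_rate": 0, "rebound_duration": 0,
      "rebound_delay": 0
    },
    "II": {
      "ca_rest": 50, "delta_ca_per_ap": 0.9, "k_leak": 0.3,
      "pump_vmax": 90, "pump_km": 150,
      "aps_per_stimulus": 1, "burst_rate": 100, "refractory_period": 0.002,
      "failure_recovery_time": 0, "rebound_rate": 0, "rebound_duration": 0,
      "rebound_delay": 0
    }
  }
}
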