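{
  "name": "eag_sh",
  "description": "eag Sh double mutant (or 4-AP + quinidine): extreme hyperexcitability with high-frequency repetitive firing (> 100 Hz) per stimulus, giant single-pulse signals in type Is; occasional post-train rebound discharge in type II.",
  "placeholder_note": "Burst counts are illustrative; chosen to reproduce the single-pulse giant-signal hallmark, not fitted to any measured table.",
  "types": {
    "Is": {"aps_per_stimulus": 20, "burst_rate": 120},
    "Ib": {"aps_per_stimulus": 6, "burst_rate": 120},
    "II": {"aps_per_stimulus": 3, "burst_rate": 120,
           "rebound_rate": 50, "rebound_duration": 0.3, "rebound_delay": 1.2}
  }
}
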