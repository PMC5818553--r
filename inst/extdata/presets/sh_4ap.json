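{
  "name": "sh_4ap",
  "description": "Shaker mutation or 4-AP block of A-type K+ current: moderate supernumerary firing, strongest in type Is terminals.",
  "placeholder_note": "Burst counts are illustrative; chosen to reproduce the qualitative enhancement hierarchy, not fitted to any measured table.",
  "types": {
    "Is": {"aps_per_stimulus": 4, "burst_rate": 100},
    "Ib": {"aps_per_stimulus": 2, "burst_rate": 100}
  }
}
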