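{
  "name": "tea_shab",
  "description": "TEA block or Shab RNAi knockdown of delayed-rectifier K+ current: burst firing and post-train rebound discharge, hallmark of type II terminals.",
  "placeholder_note": "Burst and rebound parameters are illustrative; chosen to reproduce the type II burst/rebound hallmark.",
  "types": {
    "II": {"aps_per_stimulus": 8, "burst_rate": 120,
           "rebound_rate": 50, "rebound_duration": 0.3, "rebound_delay": 1.2}
  }
}
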