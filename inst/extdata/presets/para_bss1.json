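{
  "name": "para_bss1",
  "description": "Hyperexcitable Na+ channel allele: per-stimulus bursts plus a long post-burst refractory window, producing intermittent delivery blocks in type II terminals at high stimulus frequency.",
  "placeholder_note": "Burst count and recovery window are illustrative; chosen to reproduce the intermittent-waveform hallmark.",
  "types": {
    "II": {"aps_per_stimulus": 3, "burst_rate": 100,
           "failure_recovery_time": 0.18}
  }
}
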