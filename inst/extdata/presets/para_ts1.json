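{
  "name": "para_ts1",
  "description": "Hypoexcitable Na+ channel allele: slow recovery from inactivation causes conduction failures, most severe in thin type II axons (aborted or absent responses at high stimulus frequency).",
  "placeholder_note": "failure_recovery_time is illustrative; all failures are modeled as delivery failures at the terminal.",
  "types": {
    "II": {"failure_recovery_time": 0.2}
  }
}
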