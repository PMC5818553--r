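{
  "name": "high_ph",
  "description": "External pH 8.8: suppression of proton-countertransporting PMCA extrusion; pump scaled to 60% in all terminal types, lengthening half-decay (~0.7 s type I, ~1.1 s type II).",
  "placeholder_note": "The 0.6 pump multiplier is illustrative, set to reproduce the reported direction and rough magnitude of decay lengthening.",
  "pump_scale": 0.6,
  "types": {}
}
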