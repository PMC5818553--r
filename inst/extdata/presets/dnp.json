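{
  "name": "dnp",
  "description": "DNP protonophore (mitochondrial uncoupling): ATP-dependent clearance runs down linearly with incubation time, reaching zero at 60 min; half-decay lengthens progressively and detection thresholds shift to lower frequencies.",
  "placeholder_note": "The linear 60-min rundown is illustrative; only the direction of effect (monotone decay lengthening, threshold lowering) is asserted.",
  "pump_scale": "rundown",
  "rundown_minutes": 60,
  "types": {}
}
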