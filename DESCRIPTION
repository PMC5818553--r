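Package: presynCa
Title: Presynaptic GCaMP Signal Quantification and Forward Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for presynaptic GCaMP calcium imaging
    at bouton resolution: background-subtracted dF/F extraction, baseline
    and noise estimation, noise-gated responder calls, half-rise and
    half-decay kinetics, frequency-response summaries, waveform
    classification (normal, aborted, intermittent, no response, rebound),
    and two-channel mitochondrial colocalization. Includes a biophysically
    motivated forward simulator (stimulus trains, axonal spike delivery,
    leaky-integrator calcium dynamics with a saturable extrusion pump,
    Hill-type indicator binding, synthetic movie rendering and focal
    release-event traces) that supplies ground truth for every analysis
    stage, with scenario presets for terminal types Ib, Is and II under
    excitability and clearance perturbations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
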