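---
title: "Quantifying presynaptic GCaMP signals: model, pipeline and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic GCaMP signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynCa)
```

## The measurement problem

GCaMP indicators expressed in motor terminals report presynaptic Ca²⁺, but
what they actually integrate is *residual* cytosolic Ca²⁺ — the running
balance of action-potential-driven influx and clearance — filtered through
a cooperative, saturable binding reaction. At the larval neuromuscular
junction the three terminal classes (tonic type Ib, phasic type Is,
modulatory type II) differ in both excitability and clearance capacity, so
the same stimulus train produces very different fluorescence responses.
`presynCa` implements (i) the standard quantification pipeline for such
recordings — background-subtracted ΔF/F at bouton resolution, baseline and
noise estimation, a noise-gated responder call, half-rise/half-decay
kinetics, frequency-response summaries, waveform classification, and
two-channel mitochondrial colocalization — and (ii) a forward simulator
that generates movies and traces with full ground truth, so every stage of
the pipeline is testable without raw imaging data.

## The quantification conventions

For each bouton ROI and its paired adjacent background region:

* `f_t = f_raw − f_bg` per frame (per-frame background subtraction; a
  per-frame rather than scalar background handles slow lamp drift — the
  original convention does not specify which, and this choice is recorded
  here as an interpretation).
* Baseline `F_B` = mean of `f_t` over the **25 frames (1 s at 25 Hz)**
  immediately before stimulation onset; the frame containing the onset is
  excluded.
* `ΔF/F = (f_t − F_B)/F_B`, every frame, no smoothing.
* Baseline noise `N_B` = RMS of the baseline ΔF/F deviations, i.e. the SD
  of baseline `f_t` divided by `F_B`. Taken literally, an RMS of the raw
  baseline trace would approximately equal `F_B` itself and make a
  "200% of noise" detection gate absurd; the dimensionally consistent
  reading adopted here puts `N_B` on the ΔF/F scale.
* Peak = maximum of the **5-point running average** within the **2-s
  window** after onset (ties → earliest frame). The smoother's edge
  windows are truncated to the available samples (3 points at the ends);
  this edge rule is a package choice, pinned by tests.
* Responder gate: a bouton responds iff peak ΔF/F **strictly exceeds
  2 × N_B**; nonresponders are excluded from kinetics aggregation.
* `t½rise` = time from onset to the first linearly interpolated crossing
  of half the peak. `t½decay` = time from train end to the first crossing
  below half the **trace value at train end**. Using the value at train
  end rather than the peak keeps the measure meaningful for intermittent
  traces whose peak precedes train end; when the signal peaks at train end
  the two references coincide. If the record ends first, the value is
  censored and reported as a lower bound (excluded from means, counted in
  reports).
* QC: traces with `F_B` below an absolute floor or `N_B` above a ceiling
  are flagged and excluded; thresholds are configuration values
  (`qc_filter()` defaults), not taken from any publication. Contraction
  artifacts are a manual pass-through flag.

Grouping follows the two-grain convention: *bouton grain* pools all
boutons; *NMJ grain* averages boutons within a terminal first (terminals
behave uniformly), then across NMJs. Table cells render as
`mean ± SD (n, N)` with `n` boutons and `N` NMJs. Comparison families use
Kruskal–Wallis, Student's t, or one-way ANOVA with Fisher's LSD, with
Bonferroni adjustment `p_adj = min(1, m·p)` across the declared family —
all base-R routines; the package adds only the family bookkeeping and star
notation.

## The forward model

**Spike delivery.** Each stimulus pulse either delivers a burst of
`aps_per_stimulus` action potentials spaced `1/burst_rate` (supernumerary
firing under hyperexcitability, > 100 Hz in the extreme case) or fails
when the previous AP falls within `failure_recovery_time` of the pulse
(conduction failure from slow Na⁺-channel recovery). Two additional
conduction-block modes — a permanent block after a given number of
delivered pulses and an on/off block cycle — produce the "aborted" and
"intermittent" waveforms that the simple recovery rule cannot (it can only
alternate single pulses or silence everything after the first). Post-train
rebound discharge fires at `rebound_rate` for `rebound_duration` after a
`rebound_delay`; the delay is needed for a rebound excursion to appear
*after* the signal has decayed, as observed. The walk is deterministic
given the profile.

**Calcium.** A single compartment with

$$\frac{d\,Ca}{dt} = -k_{leak}(Ca - Ca_{rest})
  - s(t)\,V_{max}\,\frac{Ca - Ca_{rest}}{(Ca - Ca_{rest}) + K_m}
  + \Delta_{AP}\sum_i \delta(t - t_i),$$

a leaky integrator with a saturable (Michaelis–Menten) extrusion term
standing for PMCA plus mitochondria-powered uptake. The schedule $s(t)$
scales the pump: 1 for intact clearance, a constant 0.6 for PMCA
suppression at high external pH, and a linear rundown to 0 over 60 min of
simulated incubation for the DNP/azide scenarios. Integration uses exact
exponential stepping for the linear part and classical RK4 for the pump on
a grid 10× finer than the frame rate; events split their step so jump
timing is exact. Frame values are fine-grid means over the frame interval
(camera exposure integration), stamped at the exposure midpoint. Tests pin
the integrator to a 10×-finer explicit-Euler oracle within 1%.

**Indicator.** Hill occupancy $\theta = Ca^{n}/(Ca^{n} + K_d^{n})$ with
first-order relaxation toward the quasi-static value (time constant
`binding_tau`, default 80 ms), and

$$\Delta F/F = r_{max}\,\frac{\theta - \theta_{rest}}{1 + r_{max}\theta_{rest}},$$

referenced to occupancy at resting Ca²⁺ so simulator output and extractor
measurement share one convention. Shipped variants: GCaMP1.3
(K_d = 234 nM, n = 3.3), GCaMP6m (167 nM, 2.96), myrGCaMP5 (447 nM), and a
"linear" configuration (n = 1, K_d ≫ Ca, rescaled r_max) that puts the
indicator in its linear regime. The linear configuration exists because
with cooperative binding ΔF/F decay is *not* exponential in time even when
Ca²⁺ decay is — a Hill exponent n maps an exponential into a faster
power — so clearance-rate recovery (the `ln 2 / k` check) is only
meaningful where ΔF/F tracks Ca²⁺ linearly.

**Imaging.** Boutons are radially tapered disks, brightness
`f0·(1 + ΔF/F(t))·(1 − (r/R)²)`, on a uniform background with additive
Gaussian read noise (σ configurable; Poisson shot noise is deliberately
not modeled — the analysis uses only the RMS noise level, for which a
Gaussian is sufficient). Rendering is bit-deterministic given the seed.
Because ΔF/F is a ratio, the taper cancels exactly in extraction: the ROI
mean is `f0·w̄·(1 + ΔF/F)` and the baseline is `f0·w̄`, so noiseless
round trips recover ΔF/F to floating-point precision (the taper factor
matters only for absolute brightness). Defaults follow the acquisition
convention of 25 Hz, 256 × 256 px; tests use 48–108 px frames, which
changes nothing but memory.

**Focal records.** Loose-patch-style event traces: one biexponential
deflection per AP (rise constant τ/5, peak normalized to the quantal
amplitude) plus Gaussian noise at ≥ 1 kHz sampling, for tests that relate
supernumerary release events to fluorescence bursts.

## Terminal-type presets and what they encode

The wild-type preset file fixes, per terminal type, the two ordinal facts
the model is built around: clearance capacity **Ib > Is > II** (pump
V_max 180/157.5/90 nM/s over a shared k_leak = 0.3/s and K_m = 150 nM) and
per-AP influx **II > Is > Ib** (Δ_AP 0.9/0.53/0.29 nM). Resting Ca²⁺
(50 nM) and the Δ_AP values are *placeholders* — the source literature
does not quantify them at these terminals — and the preset files say so.
They were calibrated once, by the following declared procedure, and not
revisited: with the GCaMP1.3 indicator and the default trace noise
(N_B ≈ 0.02), Δ_AP per type was set so the mean peak ΔF/F at that type's
detection-threshold frequency (40/20/10 Hz for Ib/Is/II) sits at ≈ 1.6 ×
the noise SD — just above the 2 × N_B gate once the maximum-over-window
statistics of smoothed noise are accounted for — while one frequency step
lower it sits near 0.7 ×. The effective clearance rates (≈ 1.5, 1.35,
0.9 /s) put half-decay at ≈ 0.46, 0.51 and 0.77 s, the observed
magnitudes (~0.5 s for type I, ~0.7–0.8 s for type II), and the 0.6 pump
multiplier of the high-pH scenario moves them to ≈ 0.7 / 1.05 s, matching
the reported direction and rough size of PMCA suppression.

Scenario presets layer excitability changes on top: `sh_4ap` (moderate
bursts, Is-dominant), `eag_sh` (20 APs/stimulus at 120 Hz — the
single-pulse giant-signal hallmark), `tea_shab` (type II bursts plus
post-train rebound), `para_ts1` (long recovery time, conduction failure),
`para_bss1` (bursts plus long recovery → intermittent blocks), `high_ph`,
and `dnp` (pump rundown parameterized by incubation minutes, held constant
within one short record). All are labelled illustrative: they encode
directions and hallmarks, not fitted parameters.

## Waveform classification

The taxonomy (normal / aborted / intermittent / no response, plus
post-train rebound) was originally applied by eye; the classifier is an
explicit operationalization. On the smoothed trace: nonresponders are
`no_response`; during the train, once the running maximum has reached
responder grade, a drop below `(1 − drop_frac)` of the running maximum
lasting at least `min_gap` frames is a stall episode — a single terminal
episode with no recovery before train end is `aborted`, any recovered
episode is `intermittent`; after the train, an excursion above
`rebound_frac × peak` following a fall below 50% of the peak is `rebound`
(upgrading only `normal`; otherwise reported as a flag). Defaults
(`drop_frac = 0.3`, `min_gap = 3`, `rebound_frac = 0.5`) are fractional,
so classification is invariant to uniform trace scaling. All thresholds
are package definitions, fixed in tests, and make no claim about the
original visual criteria. Terminal-level consensus is the majority label,
ties broken toward the more irregular label.

## Colocalization

Green (bouton) and red (mitochondria) channels are thresholded
independently — Otsu by default, percentile/absolute available for
pinning — and a bouton (connected component of the green mask, components
below `min_bouton_px = 5` discarded as noise specks) is occupied iff at
least `min_overlap_px = 2` red pixels fall inside it. Otsu's bimodality
assumption degrades when the red foreground is a very small fraction of
the image; for sparse puncta under noise the absolute threshold
(background + 5σ) is the recommended pinning, and the tests use it. An
optional integer-shift registration maximizes mask overlap (identity by
default, mirroring manual merging).

## What the simulator does and does not emulate

It reproduces: residual-Ca²⁺ integration across trains, frequency
dependence and its ordinal structure across terminal types, indicator
cooperativity/saturation and finite binding kinetics, exposure-integrated
sampling at 25 Hz, read noise, conduction failures/bursts/rebound, and
punctate two-channel staining with known occupancy. It does not emulate:
conductance-based channel dynamics (channel effects enter only through the
excitability profile), ER/SERCA stores, Poisson shot noise, bleaching,
motion/contraction artifacts, bouton-size variation within a terminal, or
autofluorescence structure in the background. Passing tests therefore
validate the *quantification conventions* against a controlled ground
truth; they do not certify performance on real movies with motion or
structured background.

## Numerical choices and degenerate inputs

Fine grid 10× the frame rate (events split steps exactly; a grid coarser
than the burst spacing is rejected); linear interpolation for all
threshold crossings with earliest-crossing tie-break; truncated smoother
edges; `F_B ≤ 0` is a QC failure rather than an exception; zero-bouton
colocalization reports an undefined fraction; degenerate statistical
comparisons (< 2 observations in a group) are skipped with a reason;
non-finite solver states abort with the offending time. Noisy half-decay
estimates carry a small early-crossing bias (the first noisy crossing
precedes the mean crossing); at trace SNR ≥ 20 it is below one frame
(0.04 s), which is why the recovery tests inject noise at the pixel level
where ROI averaging keeps the trace-level SNR high.

## Problem sizes

Test and acceptance runs use desk-scale sizes chosen to keep the full
suite in the low minutes: 48–108 px frames, 6–14 s records at 25 Hz,
3 NMJs × 8 boutons per frequency sweep, 100-seed decay recovery, 200-run
classifier banks, 50-bouton colocalization fields. All are package
choices; the pipeline itself is size-agnostic.

## A worked example

```{r example}
preset <- scenario_preset("wt", "Ib")
protocol <- stimulus_protocol(40, record_duration = 8)
sim <- simulate_nmj(preset, protocol, n_boutons = 3, seed = 1)
kin <- lapply(sim$traces, analyze_trace, protocol = protocol)
kinetics_table(kin)[, c("bouton_id", "max_dff", "t_half_rise_s",
                        "t_half_decay_s", "responder")]
```

```{r sweep}
sweep <- run_frequency_sweep("wt", "Ib", seed = 1)
sweep$response
```

## Known limitations

Censored decay times are lower bounds, not estimates; the responder gate's
false-positive rate depends on the max-over-window statistics of smoothed
noise and is checked empirically, not assumed closed-form; preset
parameter values are ordinal calibrations, not measurements; and the
aborted/intermittent boundary is an operational rule, so traces near the
boundary carry their full evidence list for review.
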