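# intentconn

Movement-intention decoding from intracranial connectivity dynamics.

## The problem

A brain–machine interface driven by motor-cortical signals must know *when*
its user intends to move: decoders optimized on active-movement data behave
unpredictably during rest, and an unintended prosthesis movement is a
safety problem, not a nuisance. `intentconn` detects the user's movement
state — active (AS, hand grasping) versus idle (IS, rest) — not from
single-channel spectral power but from the *functional connectivity*
between primary motor cortex (M1) and dorsolateral prefrontal cortex
(DLPFC) channels of an ECoG-like multichannel recording, with a
simultaneous surface-EMG channel providing the state ground truth. It is
aimed at BMI and intracranial-electrophysiology researchers who want a
tested, scriptable reference implementation of this analysis.

## The method in brief

1. **Preprocess**: common average reference over all recorded channels,
   1–300 Hz two-way least-squares FIR band-pass, 60 Hz notch; canonical
   band filters (theta 4–7, alpha 8–13, beta 13–30, gamma 30–50 Hz).
2. **Segment**: EMG envelope (rectify + 100 ms average); threshold
   `mu + 3*sigma` from a 1 s resting window; AS intervals are debounced
   supra-threshold runs; connectivity windows are labeled by their centre.
3. **Connectivity**: plug-in histogram mutual information, 8 equal-width
   bins, natural log —
   `MI = sum P(x,y) ln[ P(x,y) / (P(x) P(y)) ]` (nats) — on 1 s windows
   stepped every 100 ms, for every pair of three networks: intra-M1
   (C(10,2) = 45 pairs), intra-DLPFC (36) and inter-regional DLPFC–M1 (90).
4. **Statistic**: the mutual information ratio of a network with N pairs,
   K active and L idle windows,
   `MIR = (100/N) * sum_p [mean_AS MI(p) − mean_IS MI(p)] / mean_IS MI(p)` (%),
   with a two-sample Kruskal–Wallis rank test on the per-pair state means.
5. **Decode**: two-class LDA on per-window gamma-band MI feature vectors
   (M1-only: 45 features; DLPFC+M1 combined: 171), permuted 10-fold
   cross-validation repeated 10 times.

A bundled synthetic-session generator produces protocol-realistic sessions
(5 min at 1000 Hz, 64-electrode montage with 10 M1 + 9 DLPFC analysis
channels, 25–39 grasps ≥ 5 s apart) with state-dependent gamma-band
coupling and a burst EMG, so the whole pipeline is testable without any
recording. See `vignettes/intentconn-methods.Rmd` for the model, its
assumptions and the numerical choices.

## Worked example

```r
library(intentconn)
report <- run_intention_pipeline(synth_config(seed = 1))
print(report)
```

```
<intention_report 'synthetic-seed1'>
  events: 30 detected; windows: 2991 (AS 247 / IS 2145)
  MIR (%) by band x network:
  band     M1  DLPFC DLPFC_M1
 theta -0.361 -0.302   -0.619
 alpha  0.401 -2.588   -0.332
  beta -0.844  0.565   -0.044
 gamma 30.900  0.293    2.752
  gamma rank tests (per-pair state means):
    M1        H =   50.60, p = 1.13e-12
    DLPFC     H =    0.71, p = 0.398
    DLPFC_M1  H =   13.16, p = 0.000286
  decoding (gamma): M1-only 98.7%, DLPFC+M1 99.2% (gain 0.4%)
```

Reading the output: all 30 simulated grasps were recovered from the EMG,
and the 300 s session yields 2991 sliding windows (247 active after strict
boundary exclusion). Connectivity rises in the active state only in the
gamma band — the band the generator couples — and only in the networks that
share a source: the M1 network (MIR +30.9 %, rank test p ≈ 1e-12) and the
inter-regional DLPFC–M1 network (+2.8 %, p ≈ 3e-4), while the intra-DLPFC
network shows no significant change (p = 0.40). The gamma-band feature
vectors decode the movement state at 98.7 % (M1 pairs alone) and 99.2 %
(DLPFC and M1 pairs together); note that permuted cross-validation over
90 %-overlapping windows is optimistic — `cross_validate(..., cv =
"blocked")` gives the conservative estimate.

Individual stages are exported (`generate_session()`,
`preprocess_recording()`, `emg_threshold()`, `detect_events()`,
`sliding_mi()`, `normalize_session()`, `mir()`, `rank_test()`,
`build_features()`, `cross_validate()`, `compare_networks()`), and a thin
command-line front end lives at `inst/cli/intentconn`
(`simulate`, `run-all`). Recordings interchange as EDF or a float-exact
Feather/JSON container; connectivity tables as TSV; results as JSON.

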