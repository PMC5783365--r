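---
title: "Methods: connectivity-based movement-intention decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based movement-intention decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A brain–machine interface driven by motor-cortical activity must know when
its user *intends* to move: a decoder optimized on active-movement data can
produce arbitrary output during rest. `intentconn` implements a pipeline
that separates the active state (AS; hand grasping, surface-EMG above
threshold) from the idle state (IS; rest) using the *functional
connectivity* between primary motor cortex (M1) and dorsolateral prefrontal
cortex (DLPFC) channels of an intracranial (ECoG-like) recording, rather
than single-channel spectral features. The premise is physiological:
movement emerges from a serial change of brain states (idle, planning,
execution, recovery), DLPFC exerts executive control over the motor system,
and the information exchanged between DLPFC and M1 should therefore wax and
wane with the movement state.

## The connectivity estimator

Dependence between two channels $X, Y$ over a short window is measured by
the plug-in histogram mutual information

$$\mathrm{MI}(X, Y) \;=\; \sum_{i,j} P(x_i, y_j)\,
  \ln\!\frac{P(x_i, y_j)}{P(x_i)\,P(y_j)} \quad (\text{nats}),$$

with each signal partitioned into 8 equal-width bins spanning its own
per-window $[\min, \max]$. MI is zero iff the binned signals are
independent, is symmetric, and is bounded above by $\ln 8 \approx 2.079$.
The estimator is computed on 1 s windows stepped every 100 ms, on the
band-filtered time-domain signal, for every channel pair of three networks:
intra-M1 (all $\binom{n_{M1}}{2}$ unordered pairs, 45 on the default
10-channel layout), intra-DLPFC (36 pairs of 9 channels) and inter-regional
DLPFC–M1 (the full $9 \times 10 = 90$ cross product).

Numerical choices worth stating:

* **Bin edges.** Equal-width over the per-window range is the default;
  because the edges adapt to each window, MI is invariant to adding a
  constant to a channel. A constant window occupies a single bin and yields
  exactly 0.
* **Bias.** The plug-in estimator is biased upward by roughly
  $(8-1)^2/2n = 0.0245$ nats at $n = 1000$ independent samples (the
  $\chi^2$ approximation of $2n\,\mathrm{MI}$). No correction is applied by
  default — the raw estimator is the quantity the downstream statistics are
  defined on — but a Miller–Madow correction
  ($-(K_{xy}-K_x-K_y+1)/2n$ over occupied cells) is available via
  `mi_config(miller_madow = TRUE)` and is the reference point for the
  independence tests.
* **Trailing window.** An incomplete final window is dropped, never padded;
  a $T$-second session yields $\lfloor (T-1)/0.1 \rfloor + 1$ windows
  (2991 at $T = 300$).

The sliding-window kernel is compiled (Rcpp) because the default session
evaluates MI $2991 \times 171 \approx 5 \times 10^5$ times; a naive R loop
oracle in the test suite pins the kernel to $10^{-12}$.

## Preprocessing

The conditioning chain is fixed and ordered: common average reference
(subtract the instantaneous mean over *all recorded* channels), 1–300 Hz
band-pass, 60 Hz notch, then per-band filters (theta 4–7, alpha 8–13,
beta 13–30, gamma 30–50 Hz). When the montage carries non-analysis
channels, the reference uses the full montage and the filters run on the
analysis subset — referencing against a large montage matters, because a
reference built from few channels re-injects shared sources into every
channel and can distort between-region dependence.

Band-pass filters are linear-phase FIR designed by least squares
(pass/stop bands with don't-care transitions of 15 % of each edge
frequency). Length combines the classic three-cycles-of-the-low-edge
heuristic with a narrow-band floor,
$\max(3 f_s/f_{\mathrm{low}},\; 6 f_s/\mathrm{BW},\; f_s)$ rounded up to
odd, so the 3 Hz-wide theta band keeps its pass-band ripple well under 1 %
(the bare three-cycle rule gives a 101-tap gamma filter with ~7 % ripple).
Application is two-way: the
spectrum is multiplied by $|H(f)|^2$, exactly a forward plus a backward
pass of the symmetric FIR, giving zero net phase; edge transients are
absorbed by odd-reflection padding of three filter lengths. The 60 Hz notch
is a second-order IIR (≈3 Hz wide at −3 dB) applied forward–backward. The
1–300 Hz broadband step is retained for fidelity to the full chain even
though all analysis bands sit below 50 Hz.

## State segmentation from the EMG

The EMG envelope is full-wave rectification followed by a centred 100 ms
moving average. A 1 s resting window gives $\mu$ and $\sigma$ of the
envelope and the activity threshold $\mu + 3\sigma$. Active intervals are
maximal runs of envelope above threshold after debouncing (runs < 200 ms
dropped first, then gaps < 200 ms bridged — in that order, so an isolated
noise blip can never extend an event). The baseline window is chosen
automatically by a two-pass rule: a provisional upper fence
($q_{75} + 3\,\mathrm{IQR}$ of the envelope) flags bursts, and the first
1 s interval at least 1 s from any burst becomes the baseline.

Connectivity windows are labeled AS if their *centre* lies inside a
detected event and IS otherwise. Because a 1 s window can straddle a state
transition, the default `strict` policy excludes straddling windows from
statistics and training; a `center` policy (no exclusions) is available,
since published practice does not always state the handling. The choice is
recorded in the result object.

Event-locked temporal dynamics use session-normalized MI (per-pair min–max
over all windows — per-pair, because the dynamics of interest are within a
pair's own range), epochs of $[-2000, +500]$ ms around onsets and
$[-500, +2000]$ ms around offsets (26 frames at the 100 ms step), and a
strong-edge count at normalized MI > 0.8.

## The MIR statistic and its test

Per network with $N$ pairs, $K$ AS windows and $L$ IS windows,

$$\mathrm{MIR} = \frac{100}{N} \sum_{p=1}^{N}
  \frac{\frac{1}{K}\sum_a \mathrm{MI}_{AS}(p,a) -
        \frac{1}{L}\sum_b \mathrm{MI}_{IS}(p,b)}
       {\frac{1}{L}\sum_b \mathrm{MI}_{IS}(p,b)} \;(\%),$$

the mean per-pair relative increase of active over idle connectivity. MIR
is invariant to a global rescaling of MI, exactly 0 when every pair's state
means are equal, and positive when every pair increases. Significance is
assessed with a two-sample Kruskal–Wallis rank test (tie-corrected, 1 df)
whose analysis unit is the **pair**: one state-mean MI value per pair per
state, so group sizes equal pair counts (45/36/90 on the default layout).
Pooling windows instead would inflate $n$ by the strong autocorrelation of
90 %-overlapping windows; per-window pooling is available behind a flag but
is not the default. No multiple-comparison correction is applied across
bands or networks.

## Decoding

Feature vectors are the per-window MI values of all pairs in the chosen
network set (gamma band by default): 45 columns for M1-only,
45 + 36 + 90 = 171 for the combined DLPFC+M1 set. Windows labeled EXCLUDED
are dropped. The classifier is two-class LDA — class means, pooled
within-class covariance, linear rule with training-frequency priors — with
a small shrink of the covariance toward its diagonal
($\gamma = 10^{-4}$), needed because 171 features can approach the row
count on short sessions.

Accuracy is estimated by permuted 10-fold cross-validation repeated 10
times (rows permuted by a seeded RNG, 10 near-equal blocks, every row
tested once per repeat; mean ± SD over the 100 folds). Two caveats are
deliberately surfaced rather than hidden:

* **Temporal leakage.** Overlapping windows place nearly identical rows in
  train and test under permuted CV, which is optimistic. A
  `cv = "blocked"` mode (contiguous blocks, no permutation) is provided for
  honest estimates; the package reports whichever is requested and the test
  suite checks that blocked is never the more optimistic of the two.
* **Class imbalance.** Idle windows outnumber active ones roughly 9:1 on
  the default protocol, so prior-sensitive accuracy has a chance level well
  above 50 %. `balance_classes()` subsamples the majority class for
  chance-level controls.

## The synthetic session generator

The generator produces the study conditions end to end: a 300 s session at
1000 Hz; a 64-electrode montage of which 10 M1 + 9 DLPFC channels are
analysed (the rest participate in the reference only); 30 self-paced grasps
(protocol range 25–39) of 1.0–2.5 s with onset-to-onset gaps ≥ 5 s, kept
5 s from the session edges; and a surface-EMG trace.

Each channel is 1/f-shaped broadband noise with mild 10 and 20 Hz
oscillatory bumps. State-dependent coupling is injected as shared gamma
(30–50 Hz) sources scaled by a piecewise-linear coupling profile: baseline
0.05 at rest, a linear ramp to 0.8 starting 600 ms before each onset, a
plateau during the grasp, and a 600 ms decay after offset — the
pre-movement rise mirrors readiness-potential-like anticipatory dynamics.
Source routing sets the network ordering the analysis should detect:

* one gamma source shared by all M1 channels (gains |0.6–1.0|) — strong
  intra-M1 synchrony;
* one gamma source *per DLPFC channel* (gains |0.5–0.9|), each of which is
  also mixed into every M1 channel (weights |0.15–0.35|) — inter-regional
  transmission with an exactly null intra-DLPFC dependence, since two
  DLPFC channels share no source;
* per-electrode source polarity is random (dipole orientation varies
  across a grid), which MI ignores but which keeps the sources out of the
  common average;
* source amplitudes are expressed in units of the background's gamma-band
  SD, measured during generation, so coupling coefficients are
  dimensionless and comparable across noise settings.

Coupling as shared-source *mixing* (not phase coupling) was chosen because
binned MI measures generic statistical dependence; amplitude mixing is the
simplest mechanism that produces it. The paper-style effect sizes are not
reproducible without the original recordings, so gains were fixed once to
produce the qualitative pattern robustly (M1 and DLPFC–M1 contrasts
significant at $\alpha = 0.01$, DLPFC not; gamma the largest M1-network
MIR among the four bands) and are not tuned per analysis.

The EMG is rest noise whose amplitude carries a slow (2.2 Hz) tone
modulation — as in a resting muscle, the baseline is not perfectly
stationary — plus burst noise (gain 6) spanning each grasp with 20 ms
cosine ramps. The tone modulation dominates the resting envelope SD, which
places the $\mu + 3\sigma$ threshold well clear of instantaneous noise
excursions; with the default settings, detection recovers the simulated
events 1:1 with boundary errors below 100 ms (dominated by the ±50 ms
smear of the centred envelope window).

What the generator does **not** emulate: 1/f knee structure and
non-stationary background power, true oscillatory phase coupling, volume
conduction, electrode artifacts beyond an optional 60 Hz sinusoid
(`line_amp`, used to exercise the notch), EOG contamination, and
behavioural variability beyond trial timing. Green tests on synthetic
sessions therefore demonstrate that the *pipeline* recovers a known
embedded structure — not that real cortical recordings carry that
structure.

## Problem sizes used in the checks

The packaged checks run the full default session (300 s, 64 channels,
2991 windows, 171 pairs) across 20 seeds for the network-contrast,
band-selectivity, segmentation-recovery and decoding properties, and
smaller toy recordings (seconds long) for estimator-level oracle
comparisons. The acceptance script analyses one full default session per
run.

## Known limitations

* EDF interchange quantizes to 16 bits over each channel's physical range;
  the native Feather container is float-exact and preferred for
  intermediates.
* The `.MAT` deposit of the original study is not importable here; recorded
  data enter via EDF or the native container with a user-supplied region
  map.
* The histogram MI estimator is biased at finite $n$; comparisons across
  conditions with equal window length are unaffected, but absolute MI
  values should not be read as unbiased dependence measures.
* Permuted-CV accuracies on overlapping windows are optimistic (see
  above); use blocked CV when an unbiased deployment estimate matters.
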