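---
title: "Methods: feedback-driven value iteration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feedback-driven value iteration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters that matter, what the
synthetic-data generator emulates (and deliberately does not), and the
numerical choices made where the underlying conventions were genuinely
open.

```{r setup, message = FALSE}
library(accvi)
```

## 1. Task structure and behavioral metrics

A trial is a 1-s pure tone (3 kHz or 12 kHz), a 2-s response window, and a
4–6 s inter-trial interval. Licking the go cue yields reward (Hit),
withholding is a Miss; licking the no-go cue is punished (false alarm,
FA), withholding is a correct rejection (CR). Session compositions:
Stable and Re-stable 50/50 go/no-go; Uncertain 40/40/10/10
go/no-go/reward-omission (RO)/un-cued-reward (UR); Reversal 50/50 with the
tone–outcome mapping swapped.

Discrimination is summarised by d′ = Φ⁻¹(Hit rate) − Φ⁻¹(FA rate). Two
conventions needed fixing:

* **Hit-rate bookkeeping.** Correct licks on RO trials count toward the
  Hit rate and RO trials count in the go-trial denominator: the animal's
  choice was correct; only the experimenter withheld the reward.
* **Degenerate rates.** A perfect session has Hit rate 1 or FA rate 0 and
  an infinite d′. Rates are clipped to `[1/(2n), 1 − 1/(2n)]`, the
  standard finite-sample correction; it only engages at exactly 0 or 1.
  The proficiency flag is the inclusive threshold d′ ≥ 1.5.

**Phase splits.** Sessions are split into contiguous phases T1–T3 (thirds
for Stable/Uncertain/Re-stable; 15/35/50% for Reversal, concentrating
resolution where re-learning happens). Boundary *i* falls after trial
`round(cum_fraction_i × n)` with round-half-up and the last phase
absorbing the remainder — whether such splits use floor or round at
non-divisible *n* is not standardised anywhere, so the choice is recorded
here and the boundary indices are exposed as an attribute. Early/late
periods pool T1+T2 vs T3 (Uncertain, 67/33%) or T1 vs T2+T3 (Reversal,
15/85%).

## 2. Calcium processing

Fluorescence arrives as a neurons × trials × frames tensor at 30 frames/s,
frames spanning −2 to +4 s around stimulus onset. Time convention
throughout the package: frame 0 is stimulus onset, windows are half-open
`[start, end)` in seconds, and a time maps to the frame with
`floor(t × rate)`.

* **ΔF/F** = (F − F₀)/F₀, with F₀ the mean of the baseline samples lying
  between the 25th and 75th percentile of the 2-s pre-stimulus window.
  Percentiles use linear interpolation between order statistics with an
  inclusive mask (q25 ≤ x ≤ q75) — the most common convention; the unit
  tests pin it against a brute-force sort/mask oracle. Trials with F₀ ≤ 0
  are flagged invalid and excluded downstream rather than patched.
* **z-scoring** subtracts the mean of the 0.5 s before the aligned event
  and divides by its sample (n − 1) standard deviation. Zero-variance
  baselines are flagged invalid.
* **0–1 mapping and 5 Hz low-pass** belong to raw-trace extraction. No
  signal-processing package is available in the target environment, so
  the low-pass is implemented as a zero-phase frequency-domain filter
  with a 4th-order Butterworth magnitude response: exactly no phase
  shift, and −24 dB at 10 Hz for a 5 Hz cutoff, satisfying the ≥20 dB
  contract the tests check. Whether the 0–1 mapping precedes or follows
  ΔF/F in the original processing chain is ambiguous; the package
  applies raw → map → filter → ΔF/F and records that order here. The
  synthetic generator emits already-extracted traces, so this step is
  optional (`preprocess = FALSE` by default in `process_calcium()`).
* **Responsiveness** is a paired Wilcoxon signed-rank of per-trial
  stimulus-window means against 2-s baseline means (P < 0.05), with the
  direction (activated/suppressed) from the sign of the median
  difference. The normal approximation is used for speed; its type-I
  error calibrates to 0.05 ± 0.01 over 10,000 null simulations in the
  acceptance suite.
* **Onset detection** smooths each trial with a 3-frame moving average
  and takes the first stimulus-window frame whose across-trial values
  differ from pooled baseline means at P < 0.01 (rank-sum). When no
  frame reaches significance the onset is *undefined* (`NA`) rather than
  clamped — fabricating latencies biases downstream statistics.

## 3. Functional classes and selectivity

All four classification contexts use one inequality, the 2-fold rule
R₁ − R₂ > |R₂| (for positive R₂ exactly "R₁ at least twice R₂"); the
absolute value keeps it meaningful when the reference response is
negative. Contexts:

| session | class | R₁ | R₂ |
|---|---|---|---|
| Uncertain | outcome monitoring | RO response (1 s after first lick) | Hit response |
| Uncertain | value updating | go-cue response, early (67%) | late (33%) |
| Reversal | outcome monitoring | air-puff response, early (15%) | late (85%) |
| Reversal | value updating | no-go-cue (3 kHz) response, early | late |

Dual-function neurons satisfy both rules. Neurons with fewer than 3
trials in a required condition or invalid window means are excluded and
counted. By default every neuron is classified; the pipeline restricts to
neurons passing the responsiveness screen (`responsive_only`), because
for a neuron with no response at all both sides of the rule are noise
around zero and the inequality degenerates to a biased coin — the screen
is precisely the guard for that case.

The go/no-go **selectivity index** is SI = (R̄_go − R̄_nogo)/σ_p with σ_p
the pooled standard deviation. As printed, the pooling formula yields a
variance though it is named a standard deviation; the square root is
taken. Significance comes from 1,000 trial-label shuffles; the test is
two-sided via |SI| (a neuron preferring either cue counts), with
significance when |SI| exceeds the 95th percentile of the shuffled |SI|.

## 4. Population geometry

Trial-averaged z-scored responses from −0.5 to 1 s around onset are
stacked (time × condition rows, neuron columns), column-centered, and
embedded by one SVD-based PCA shared across all conditions and sessions,
so trajectories live in a single comparable space. Trajectory length is
the summed Euclidean step length in PC1–3 over the stimulus window;
distance between two trajectories is the summed pointwise Euclidean
distance. For sampling distributions, a bootstrap draws 40 neurons
without replacement ("a random set of" reads as sampling distinct
neurons; with-replacement is available by flag), rebuilds the matrix and
**re-fits the PCA** in each of 5,000 iterations — whether the embedding
is re-fit per draw is not specified anywhere, and re-fitting is the
honest choice because a fixed embedding would leak full-population
structure into the subsample; a `refit = FALSE` flag provides the other
convention. Population similarity across phases/sessions is the Pearson
correlation of neuron-indexed vectors of trial-averaged window responses.

## 5. Decoding

The environment provides no SVM implementation, so the linear
maximum-margin classifier is implemented in-package as L1-loss dual
coordinate descent (the liblinear algorithm) with fixed C = 1; features
are standardized on the training split only. Within-scope decoding uses
3-fold cross-validation (two-thirds train / one-third test) repeated with
fresh fold draws; cross-scope decoding trains on the source scope
(resampling two-thirds of it per repeat) and evaluates every test-scope
trial. Accuracy is the zero-one loss. Class imbalance is handled by
subsampling the majority class per repeat. Features are per-trial
window-mean responses (0–1 s post-event) rather than full time courses —
the windowed means are what the classification and outcome analyses use,
and a config switch is unnecessary complexity while the contracts hold.
Because pooled neurons were not recorded simultaneously, population
decoding assembles *pseudo-trials*: each neuron contributes the window
mean of one of its own same-class trials, drawn with replacement; classes
are balanced by construction. Cohort comparisons (e.g. with vs without
dual-function neurons) draw the same number of neurons (default 200) from
each cohort per repeat, 5-fold cross-validation, 1,000 repeats.

## 6. Outcome-history regression

Two linear models quantify history effects on per-trial go-cue responses:

* **History model**: f(t) = α + Σᵢ₌₁..₅ wᵢ·O₍t−i₎, with O = 1 for
  non-reward and 0 for reward. Fit by OLS; the first five trials lack a
  full history and are dropped, not zero-padded (padding would shrink the
  lag estimates toward zero). Rank deficiency (e.g. constant outcomes) is
  flagged rather than silently resolved. Group-level inference is a
  one-sample two-sided signed-rank of each lag's weights across neurons,
  plus a rank-sum between sessions; this assumes per-neuron fits are
  aggregated afterwards (the plausible reading) rather than one pooled fit.
* **Task-variable model**: stimulus (constant 1, the model's intercept
  role), cumulative history (fraction of the session's unexpected trials
  already experienced, 0–1), previous outcome (1 if the previous trial
  was unexpected), and licking rate. Explained variance is cross-validated
  (5-fold); held-out R² uses the held-out fold's own total sum of squares
  and negative values are reported as-is. A variable's contribution is the
  drop in cross-validated R² when it is removed, on identical folds. The
  licking-rate window is not defined anywhere; the package uses licks/s
  inside the stimulus window, computed from the stored first-lick time and
  lick count under a constant-rate convention (see §7).

## 7. The SARSA model with adaptive learning rate

Only 3 kHz-tone trials are modelled: Q = (Q_lick, Q_nolick) is the
incentive value of that tone under the two actions. Per modelled trial:
P(lick) from the softmax with scaling β; the outcome follows the session
rule (Hit/Miss/RO under the original contingency, FA/CR after reversal);
Δr = R − Q(chosen); Q(chosen) += α·Δr with the unchosen value untouched
(the update equation is action-indexed; the compressed notation of the
learning-rate equation is read as a time-update of the chosen action's
value). The learning rate iterates as αₜ = θ′αₜ₋₁ + θ|Δrₜ₋₁|.

Numerical and interpretive choices:

* **First trial.** α₀ = 0.1 is the *state* of the first modelled trial:
  trial 1 updates with α = α₀ and produces Δr₁; α₂ = θ′α₀ + θ|Δr₁|. This
  matches the worked arithmetic the tests pin (first Hit from Q₀ gives
  Δr = 0.02 and a next-trial rate of 0.6×0.1 + 0.08×0.02 = 0.0616).
* **Clamping.** α is clamped to [0, 1]: with R(FA) = −2 the iteration can
  otherwise exceed 1 (θ|Δr| alone reaches ~0.24 and compounds), which
  would make Q overshoot its target and oscillate.
* **Miss trials** update the chosen (no-lick) action with R(Miss); a
  config in which they update nothing is representable by zeroing that
  reward-map entry.
* **β is fixed** at the published per-session values (2.3 / 1.68); the
  procedure that derived them from experimental performance is not
  reconstructed.

With θ = 0, αₜ = θ′ᵗα₀ exactly; with constant reward and fixed α,
|Qₜ − R| = (1−α)ᵗ|Q₀ − R| exactly — both are enforced to 1e-12 in the
acceptance suite, as is the ordering mean α(early Reversal) >
mean α(Uncertain) > mean α(Stable) at the published parameters, with the
Stable late-session mean below 0.01.

**Parameter recovery** maximizes the Bernoulli log-likelihood of the
observed lick sequence over (θ′, θ, β) by a coarse grid followed by
L-BFGS-B refinement; Q₀, α₀ and the reward map stay fixed. The recovery
study simulates 200 sessions × 100 modelled trials under the **Reversal**
contingency: the session type is not prescribed, and Reversal is the
informative choice because large prediction errors are what expresses the
adaptive-learning-rate parameters — Stable sessions barely move α and
leave θ′, θ weakly identified. Recovery lands within a few percent of
truth; the acceptance bound is ±20%.

## 8. What the synthetic generator emulates — and what it does not

`simulate_dataset()` builds, per session: a trial sequence matching the
composition exactly (largest-remainder rounding, uniform shuffle, ITI
uniform on 4–6 s); agent behavior from the SARSA policy on 3 kHz trials
(other tones lick with a fixed, session-appropriate probability: 0.05
when the tone is a trained no-go, 0.5 during reversal re-learning, 0.9
when it is the re-learned go cue); and a fluorescence tensor. Each trace
is baseline + transients with instant rise and single-exponential decay
(τ = 0.4 s, GCaMP6f-like — the simplest kernel that preserves
window-mean structure) at cue onset and outcome delivery, plus i.i.d.
Gaussian noise (σ = 0.1 on a ΔF/F-comparable scale; reference SNR for
the recovery criteria).

Planted structure, with full ground truth returned:

* outcome-monitoring neurons scale unexpected-outcome responses by a
  gain drawn from U(3, 4) — comfortably beyond the 2-fold rule;
* value-updating neurons divide their value-cue response (history
  modulation included) by U(3, 4) in the late period, only in sessions
  whose unexpected outcomes drive re-assessment (Uncertain, Reversal);
* dual-function neurons are a planted subset of both;
* history weights wᵢ follow a decaying template scaled per neuron;
* class counts use round-half-up on the configured mix (defaults
  0.33/0.21/0.07, the recorded-population proportions).

Deliberately **not** emulated: spiking or spike-to-calcium nonlinearity,
neuropil and motion artifacts, correlated noise across neurons,
within-window lick dynamics (lick times are a flagged modeling
convenience: onset uniform on 0.6–1.8 s, outcome at the first lick inside
the response window, licks spread at a constant rate for the lick-rate
regressor), and session-to-session drift in neuron identity. A green test
therefore establishes that the *analysis chain* is correct and calibrated
on data with the assumed statistical structure — not that real recordings
satisfy those assumptions.

RO behavior follows the session rule: an RO trial is a go-cue trial whose
correct lick triggers reward omission; UR trials deliver reward at a
fixed 1.5 s latency with no tone and no modelled choice.

## 9. Reproducibility and degenerate inputs

Every random draw flows from one master seed through named substreams
(`substream_seed(seed, "module/purpose")`), so modules can be re-run
independently and `run_pipeline()` is byte-reproducible for a fixed
configuration. All seeds stay below 2³¹. Degenerate inputs have defined
behavior rather than silent repair: constant traces map to zero with a
warning, invalid F₀ or zero-variance baselines flag the neuron/trial,
empty decoding classes and undersized cohorts raise typed errors, and
rank-deficient regressions mark the affected coefficients undefined.

## 10. Known limitations

* The SVM and Butterworth-magnitude filter are in-package implementations
  (no suitable dependency exists in the environment); both are pinned by
  analytic contracts in the tests, but they are not drop-in replacements
  for liblinear/filtfilt in every corner case (e.g. the FFT filter's
  periodic boundary handling).
* The Re-stable agent re-learns from Q₀ within the session rather than
  starting proficient at the new contingency; its early-session behavior
  is therefore closer to a second reversal than to a consolidated
  Re-stable session. Analyses that depend on Re-stable use only its
  steady-state properties.
* Parameter recovery assumes the reward map and initial state known; in
  real fitting these would be nuisance parameters.
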