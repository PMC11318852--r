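---
title: "sepsiswatch: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sepsiswatch: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiswatch)
```

# The problem

Sepsis is life-threatening organ dysfunction driven by a dysregulated host
response to infection; every hour of delayed treatment measurably raises
mortality. An ICU early-warning model is only useful if it is early *and*
quiet: systems that page clinicians on every transient probability spike
get ignored (alert fatigue). `sepsiswatch` implements a complete pipeline
for this problem — hourly PSV records in, timed alerts and evaluation
reports out — with the false-alarm-suppressing warning/alert logic as a
first-class component rather than an afterthought.

# Data model and preprocessing

A patient is an hourly matrix of 8 vitals and 26 labs with an ICULOS hour
clock, static demographics, and a monotone per-hour sepsis label.
Exclusions: stays under 8 h, septic onsets before hour 4, truncation at
336 h. These rules exist because a 4 h window plus a 6 h lookahead are
meaningless on shorter stays, and multi-week stays otherwise dominate the
hourly evaluation.

**Sample-and-hold imputation.** Each observed value is carried into
subsequent missing hours for at most 4 h (vitals) or 24 h (labs) — the
time scales on which those measurements are clinically considered current.
Holds are per-parameter, restart at every fresh observation, never
overwrite observed cells, and the operation is idempotent. Cells that
remain missing become the sentinel −1 (`imputation_policy(fill_value=)`
controls this; the pipeline keeps them `NA` until after the raw-unit
derived features are computed, then lets normalization emit the sentinel).

**Normalization.** Min–max rescaling to [1, 5] with data-independent,
clinician-plausible limits per parameter (shipped in
`inst/extdata/feature_config.yaml`; out-of-range values truncate to the
nearest limit; missing maps to −1). The limits are constants, never fitted
to data — refitting per cohort would leak test information and break
cross-site comparability. The narrow [1, 5] band keeps small physiological
shifts visible to the classifier while −1 stays unambiguously outside it.

**Features.** Parameters wholly unobserved in more than 80% of patients
are dropped, then the configured final set is used: HR, O2Sat, Temp, SBP,
MAP, DBP, Resp; WBC, Platelets, Creatinine, BUN, total bilirubin, Lactate,
Glucose, Hct; Age, Gender; plus four derived parameters — shock index
(HR/SBP), BUN/creatinine ratio, MEWS, and a partial SOFA restricted to
MAP, bilirubin and platelets. The selection covers each major organ system
with at least one parameter. The exact lab subset and the normalization
limits are declared package defaults (configurable), chosen for organ
coverage and routine availability; different hospitals could reasonably
substitute their own, which is why both live in editable YAML rather than
code.

**Targets and windows.** Labels are shifted 6 h ahead of onset so a
correct prediction at the shifted hour is a 6 h early warning. Input is
overlapping 4 × 21 windows ending at each hour from 4 onward; no padding
is used, so predictions begin at hour 4. Negative windows are undersampled
to a 1:1 ratio against positives, pooled across the whole negative cohort
so the retained negatives stay heterogeneous.

# Classifier

A single-layer LSTM (64 units by default) over the 4 timesteps, with:

* **masking** — a timestep whose 21 features all equal −1 contributes
  nothing: hidden and cell state pass through unchanged, exactly
  equivalent to deleting the timestep (verified in tests);
* **layer normalization** of the final hidden state, stabilizing its
  scale before the head;
* a ReLU dense layer (32 units) and a sigmoid output, trained with binary
  cross-entropy under Adam (lr 1e-3, batch 128, 50 epochs by default).

The forward and backward passes are written directly in vectorized R; the
analytic gradients are checked against central finite differences to
relative error < 1e-5 in the test suite. Training is exactly reproducible
from the config seed, and all seeded package functions restore the
caller's RNG state. Defaults were sized for CPU minutes: the full
500-patient recovery experiment trains in seconds.

Hyperparameters are declared choices, not tuned values — the architecture
is deliberately small because the input is only 4 × 21 and the synthetic
signal is strong. "Attention" in the broader literature on such models is
read here as the LSTM's own gating; no separate attention block is
implemented.

# Warnings, alerts, lookahead

A **warning** fires at every hour whose probability strictly exceeds 0.5
(ties at exactly the threshold do not warn; with continuous scores the
boundary is measure-zero, and strictness makes the quiet default
explicit). An **alert** fires at the earliest hour t with at least x = 3
warnings inside the inclusive trailing window [t − w + 1, t], w = 5; the
alarm latches at its first firing. The window slides over *clock* hours,
not prediction indices, so hours without predictions (before hour 4) still
age warnings out. The earliest qualifying hour is necessarily itself a
warning hour, which the implementation exploits; an exhaustive per-hour
scan is kept in the tests as the independent oracle. Lookahead is
onset − alarm hour (positive = early). `sweep_policy()` re-derives alerts
over an (x, w) grid; for fixed w, raising x can only remove alerts, so
patient-level positives are provably non-increasing in x — the suite
checks this on every fixture.

# Evaluation

Time-level metrics compare hourly probabilities against shifted targets;
patient-level metrics compare "any alert during the stay" against sepsis
status. The false-alarm ratio is FP/(TP + FP) × 100 with the convention
0/0 → 0 (no alarms raised means no false alarms). AUROC uses midrank tie
handling (Wilcoxon form of the trapezoidal area) and AUPRC uses step
interpolation over descending thresholds; both are verified against a
quadratic-time pairwise oracle. A prevalence-matched test set pairs
`round(neg · p/(1 − p))` positives with a given negative count.

**Utility score.** Per hour: a positive prediction on a septic patient
earns a reward ramping linearly from 0 at onset − 12 h to 1 at
onset − 6 h, decaying to 0 at onset + 3 h (positives even earlier than
12 h cost the false-positive penalty); a negative prediction costs nothing
until onset − 6 h, then ramps to −2 at onset + 3 h and saturates there; a
false-positive hour on a non-septic patient costs 0.05. The cohort total
is normalized between two anchors evaluated on the same cohort: the
all-negative predictor (0) and the *reference ideal* predictor that turns
positive exactly 6 h before each onset (1).

This anchored normalization is a deliberate design decision: the reference
is the clinically ideal behavior the 6 h label shift trains toward, and it
makes the score's fixed points exact. It is an anchor, not a supremum — a
predictor that additionally fires during the 12→6 h ramp-up collects extra
reward and can exceed 1. The invariant the package asserts is therefore
the practical one (random and realistic predictors score ≤ 1; the anchors
are exact), not a global maximality claim. All constants
(`utility_params()`) are configurable.

# Synthetic cohort generator

The generator's defaults are the study conditions for the whole test
suite:

* stays ~ lognormal(meanlog log 42, sdlog 0.5) clipped to [8, 336] h — a
  right-skewed stay distribution with a median of about 1.75 days;
* vitals/labs as first-order mean-reverting (AR1, φ = 0.9) series around
  clinician-plausible set-points, the simplest process with realistic
  hour-to-hour autocorrelation;
* labs observed every ~24 h at a random per-patient phase; EtCO2,
  TroponinI, Fibrinogen and direct bilirubin present in only ~15% of
  patients (so the 80% feature-selection rule has real work to do);
  additional missing-completely-at-random thinning calibrated analytically
  so the overall raw missing fraction hits 0.79;
* sepsis prevalence 0.0726 (binomial per patient; at least one positive is
  forced when prevalence is positive so tiny cohorts stay usable); onset
  uniform from hour 5 to discharge;
* a monotone linear drift starting 10 h before onset and holding after it,
  default 2.5 z-units on HR (+), SBP (−), Resp (+), Temp (+), WBC (+),
  Lactate (+), Creatinine (+), Platelets (−).

The MCAR mechanism is declared, not hidden: real ICU missingness is
informative (sicker patients get measured more), and the generator makes
no attempt to emulate that, nor multi-organ trajectory correlations,
treatment effects, or calibrated inter-measurement gap distributions. A
passing suite therefore demonstrates that the pipeline's machinery is
correct and that the classifier can recover a learnable pre-onset signal —
not that any particular real-data performance level would be attained.

# Problem sizes and numerical choices

The test suite runs on cohorts of 40–80 patients for module tests, 200 for
the missingness calibration check, 1000 for the prevalence check, and 500
(the package's standard recovery experiment) for the held-out classifier
check, where window-level AUROC on unseen patients must exceed 0.85; the
observed value at the fixed seed is ≈ 0.98. Band-table boundaries resolve
to the first matching rule in listed order (so a shared boundary belongs
to the band listed first); missing score components contribute 0 points —
the only computable policy at 79% missingness, stated openly. Degenerate
inputs error early and loudly: non-contiguous hour clocks, non-monotone
labels, out-of-range probabilities, single-class training sets, degenerate
normalization limits.

# Known limitations

* The generator's realism is deliberately limited (see above); absolute
  metric values on synthetic cohorts say nothing about real cohorts.
* The partial SOFA omits vasopressor tiers, respiratory and renal
  components, and the comparator thresholds (SIRS ≥ 2, NEWS ≥ 7, MEWS ≥ 4,
  pSOFA ≥ 2) are common clinical defaults, configurable because no single
  standard exists.
* Alarm de-escalation after clinical intervention is not modeled; the
  alarm simply latches.
* The stratified split option exists but defaults off; with unstratified
  splits, small test sets can be prevalence-skewed.
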