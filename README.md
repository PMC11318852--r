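# sepsiswatch

Early warning of hospital-acquired sepsis for ICU patients, with the alarm
logic designed around the problem that actually blocks such models at the
bedside: false alarms and the clinician alert fatigue they cause.

The package is aimed at clinical data scientists and method developers who
work with hourly ICU records in the PhysioNet/CinC 2019 pipe-separated
(PSV) layout — one file per patient, 8 vital signs, 26 lab values, 6
demographic fields, and a per-hour binary sepsis label. Because that data
is access-controlled, the package ships a synthetic cohort generator that
reproduces the *statistical regime* of such records (hourly autocorrelated
vitals, roughly daily labs, ~79% of raw cells missing, configurable sepsis
prevalence, a pre-onset physiological drift), so every stage of the
pipeline is runnable and testable out of the box.

## The method

1. **Preprocessing.** Patients with under 8 hours of data or sepsis onset
   before hour 4 are excluded; stays are truncated at 2 weeks. Missing
   values are imputed by *time-limited sample-and-hold*: an observation is
   carried forward at most 4 h (vitals) or 24 h (labs). Each parameter x is
   rescaled by clinician-set limits to

   Y = −1 if x is missing, else 4·(x − x_min)/(x_max − x_min) + 1 ∈ [1, 5],

   so missingness survives as an explicit sentinel. The model input is the
   17 selected raw parameters (7 vitals, 8 labs, age, sex) plus 4 derived
   ones — shock index HR/SBP, BUN/creatinine ratio, MEWS, and a partial
   SOFA (MAP, bilirubin, platelets) — as overlapping 4 h × 21 windows. For
   early prediction, per-hour targets are the sepsis labels shifted 6 h
   ahead of true onset; negative windows are undersampled to balance.

2. **Classifier.** A compact LSTM with a masking layer (timesteps whose
   features all equal −1 skip the recurrent update), layer normalization of
   the final hidden state, a ReLU dense layer and a sigmoid output, trained
   with binary cross-entropy under Adam. It emits one sepsis probability
   per hour from hour 4 onward.

3. **Warnings and alerts.** A *warning* fires whenever the probability
   exceeds 0.5; an *alert* fires only when x warnings (default 3)
   accumulate within a trailing w-hour window (default 5). Isolated
   spikes therefore never page anyone. The false-alarm ratio is
   FAR = FP/(TP + FP) × 100 at the patient level.

4. **Evaluation.** Time-level and patient-level confusion metrics, AUROC /
   AUPRC, lookahead times (hours between alarm and true onset), comparator
   scores (SIRS, NEWS, MEWS, pSOFA) run through the same patient-level
   evaluation, and the timeliness-aware *utility score*: each hour's
   prediction earns a reward that peaks 6 h before onset and penalties for
   late/missed detections and false positives, normalized so the
   all-negative predictor scores 0 and the predictor that turns positive
   exactly 6 h before every onset scores 1.

## Worked example

```r
library(sepsiswatch)

cfg <- run_config(
  output_dir = "run",
  cohort = cohort_config(n_patients = 300, prevalence = 0.2, seed = 1),
  model = model_config(epochs = 30),
  test_fraction = 0.25,
  seed = 42
)
state <- run_pipeline(cfg)
print(state$summary$patient)
```

```
<evaluation_report: patient level>
  tp 11 | fp 12 | tn 52 | fn 0
  sensitivity 100.00%  specificity 81.25%  accuracy 84.00%
  PPV 47.83%  NPV 100.00%  F1 64.71%  false-alarm ratio 52.17%
  normalized utility 0.933
  alert lookahead median 4 h (IQR 2.5-7.5), 0 missed
```

On this synthetic test cohort every septic patient is alerted, at a median
of 4 hours before true onset, and the utility score of 0.93 says those
alerts also came close to the ideal 6-hours-early timing. The policy sweep
written to `run/policy_sweep.tsv` shows what the alert rule buys: at w = 5,
requiring x = 1 warning gives a 65.6% false-alarm ratio, x = 3 gives
52.2%, and x = 5 gives 42.1% — stricter alert criteria trade sensitivity
for fewer false pages. The comparator table (`run/comparator_scores.tsv`)
shows hourly SIRS alarming with far worse specificity (0.39) than the
model's alerts (0.81) on the same patients.

A shell front end with the same verbs is installed at
`inst/cli/sepsiswatch`:

```sh
Rscript inst/cli/sepsiswatch run-all --n-patients 200 --seed 1 --out run
```

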