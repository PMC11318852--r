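# Default preprocessing configuration.
#
# selected_* name the 17 raw parameters kept after feature selection
# (7 vitals + 8 labs + 2 demographics); the 4 derived parameters
# (ShockIndex, BUN_CR_Ratio, MEWS, pSOFA) are appended afterwards for a
# 21-column model input.
#
# hold limits are hours an observation may be carried forward
# (sample-and-hold); normalization limits are native-unit min/max used by
# the min-max rescale to [1, 5] (values outside are truncated to the
# nearest limit first). Limits are fixed, data-independent constants.
selected_vitals: [HR, O2Sat, Temp, SBP, MAP, DBP, Resp]
selected_labs: [WBC, Platelets, Creatinine, BUN, Bilirubin_total, Lactate, Glucose, Hct]
selected_demographics: [Age, Gender]
derived_parameters: [ShockIndex, BUN_CR_Ratio, MEWS, pSOFA]
hold_limits:
  vitals: 4
  labs: 24
label_lookahead: 6
window_hours: 4
window_stride: 1
undersample_ratio: 1.0
max_missing_fraction: 0.80
mask_value: -1
normalization_limits:
  HR:              [30, 180]     # beats/min
  O2Sat:           [80, 100]     # %
  Temp:            [34, 41]      # degrees C
  SBP:             [60, 200]     # mmHg
  MAP:             [40, 140]     # mmHg
  DBP:             [30, 120]     # mmHg
  Resp:            [5, 40]       # breaths/min
  WBC:             [0, 30]       # 10^3/uL
  Platelets:       [0, 500]      # 10^3/uL
  Creatinine:      [0.2, 5]      # mg/dL
  BUN:             [5, 80]       # mg/dL
  Bilirubin_total: [0.1, 12]     # mg/dL
  Lactate:         [0.5, 8]      # mmol/L
  Glucose:         [50, 300]     # mg/dL
  Hct:             [20, 55]      # %
  Age:             [18, 100]     # years
  Gender:          [0, 1]        # binary
  ShockIndex:      [0.3, 2.0]    # HR/SBP, unitless
  BUN_CR_Ratio:    [5, 40]       # unitless
  MEWS:            [0, 13]       # points
  pSOFA:           [0, 9]        # points
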