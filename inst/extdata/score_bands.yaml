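# Band tables for the clinical severity scores. Shipped as data, not code:
# hospitals run different revisions of these tables, and editing a config
# file is safer than patching score logic.
#
# Each banded component lists rules [lower, upper, points]; a value scores
# the FIRST rule (in listed order) whose closed interval contains it, so a
# boundary shared by two rules belongs to the one listed first. "-inf"/"inf"
# mark open ends. A missing component contributes 0 points.
#
# trigger_threshold is the number of points at which the score, used as a
# stand-alone comparator alarm, raises a flag for that hour.
mews:
  trigger_threshold: 4
  components:
    SBP:   [[-inf, 70, 3], [70, 80, 2], [80, 100, 1], [100, 199, 0], [199, inf, 2]]
    HR:    [[-inf, 40, 2], [40, 50, 1], [50, 100, 0], [100, 110, 1], [110, 129, 2], [129, inf, 3]]
    Resp:  [[-inf, 8, 2], [8, 14, 0], [14, 20, 1], [20, 29, 2], [29, inf, 3]]
    Temp:  [[-inf, 35, 2], [35, 38.4, 0], [38.4, inf, 2]]
news:
  trigger_threshold: 7
  components:
    Resp:  [[-inf, 8, 3], [8, 11, 1], [11, 20, 0], [20, 24, 2], [24, inf, 3]]
    O2Sat: [[-inf, 91, 3], [91, 93, 2], [93, 95, 1], [95, inf, 0]]
    Temp:  [[-inf, 35, 3], [35, 36, 1], [36, 38, 0], [38, 39, 1], [39, inf, 2]]
    SBP:   [[-inf, 90, 3], [90, 100, 2], [100, 110, 1], [110, 219, 0], [219, inf, 3]]
    HR:    [[-inf, 40, 3], [40, 50, 1], [50, 90, 0], [90, 110, 1], [110, 130, 2], [130, inf, 3]]
psofa:
  trigger_threshold: 2
  components:
    MAP:             [[70, inf, 0], [-inf, 70, 1]]
    Bilirubin_total: [[12, inf, 4], [6, 12, 3], [2, 6, 2], [1.2, 2, 1], [-inf, 1.2, 0]]
    Platelets:       [[150, inf, 0], [100, 150, 1], [50, 100, 2], [20, 50, 3], [-inf, 20, 4]]
# SIRS is criterion-counting rather than banded points: each criterion is an
# OR over parameter conditions; the flag fires at trigger_threshold criteria.
sirs:
  trigger_threshold: 2
  criteria:
    temperature: [{parameter: Temp, op: gt, value: 38}, {parameter: Temp, op: lt, value: 36}]
    heart_rate:  [{parameter: HR, op: gt, value: 90}]
    respiration: [{parameter: Resp, op: gt, value: 20}, {parameter: PaCO2, op: lt, value: 32}]
    white_cells: [{parameter: WBC, op: gt, value: 12}, {parameter: WBC, op: lt, value: 4}]
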