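# Default synthetic-cohort specification: class-conditional marginals of the
# study population's baseline characteristics (stone vs no-stone on CT).
# Continuous-normal features carry mean/sd; right-skewed features carry
# median/q25/q75 and are fitted as lognormal (meanlog = log(median),
# sdlog = log(q75/q25) / (2 * qnorm(0.75))). Dipstick grades are ordinal 0-4;
# the source table reports only ">=1+" aggregates, so the split of mass across
# grades 1-4 is free configuration. Urine WBC has a degenerate reported spread
# (median 0, IQR 0-1) and uses a zero-inflated rounded-lognormal count instead
# of a plain lognormal; this deviation is deliberate and flagged here.
"n": 1000
prevalence: 0.85
seed: 20260428
features:
  - name: age
    family: history
    kind: continuous
    dist: normal
    support: [18.0, 95.0]
    stone:   {mean: 48.1, sd: 13.2}
    nostone: {mean: 44.4, sd: 16.6}
  - name: sex
    family: history
    kind: binary            # 1 = male
    stone:   {prob: 0.679}
    nostone: {prob: 0.553}
  - name: stone_history
    family: history
    kind: binary
    stone:   {prob: 0.315}
    nostone: {prob: 0.127}
  - name: pain_duration_h
    family: history
    kind: continuous
    dist: lognormal
    support: [0.1, 240.0]
    stone:   {median: 2.2, q25: 1.1, q75: 5.7}
    nostone: {median: 3.8, q25: 1.0, q75: 17.1}
  - name: pain_scale
    family: history
    kind: continuous
    dist: normal
    support: [0.0, 10.0]
    stone:   {mean: 5.0, sd: 2.2}
    nostone: {mean: 4.6, sd: 2.3}
  - name: nausea
    family: physical
    kind: binary
    stone:   {prob: 0.202}
    nostone: {prob: 0.107}
  - name: vomiting
    family: physical
    kind: binary
    stone:   {prob: 0.132}
    nostone: {prob: 0.053}
  - name: cva_tenderness
    family: physical
    kind: binary
    stone:   {prob: 0.608}
    nostone: {prob: 0.480}
  - name: body_temp_c
    family: physical
    kind: continuous
    dist: normal
    support: [35.0, 41.0]
    stone:   {mean: 36.5, sd: 0.4}
    nostone: {mean: 36.6, sd: 0.6}
  - name: le_grade
    family: dipstick
    kind: ordinal           # dipstick leukocyte esterase, grades 0-4
    stone:   {probs: [0.892, 0.054, 0.032, 0.016, 0.006]}   # P(>=1+) = 0.108
    nostone: {probs: [0.800, 0.100, 0.060, 0.030, 0.010]}   # P(>=1+) = 0.200
  - name: specific_gravity
    family: dipstick
    kind: continuous
    dist: normal
    support: [1.000, 1.045]
    stone:   {mean: 1.020, sd: 0.008}
    nostone: {mean: 1.019, sd: 0.008}
  - name: occult_blood_grade
    family: dipstick
    kind: ordinal           # grades 0-4
    stone:   {probs: [0.069, 0.150, 0.200, 0.250, 0.331]}   # P(>=1+) = 0.931
    nostone: {probs: [0.307, 0.250, 0.200, 0.150, 0.093]}   # P(>=1+) = 0.693
  - name: urine_rbc_hpf
    family: microscopy
    kind: continuous
    dist: lognormal
    round: true
    support: [0.0, 5000.0]
    stone:   {median: 50.0, q25: 20.0, q75: 100.0}
    nostone: {median: 20.0, q25: 1.0, q75: 100.0}
  - name: urine_wbc_hpf
    family: microscopy
    kind: zero_inflated     # deviation from plain lognormal; see header note
    round: true
    support: [0.0, 500.0]
    stone:   {p_zero: 0.60, median: 1.5, q25: 1.0, q75: 3.0}
    nostone: {p_zero: 0.60, median: 1.5, q25: 1.0, q75: 3.0}
  - name: crystalluria
    family: microscopy
    kind: binary
    stone:   {prob: 0.089}
    nostone: {prob: 0.020}
  - name: creatinine_mgdl
    family: blood
    kind: continuous
    dist: normal
    support: [0.2, 3.5]
    stone:   {mean: 1.0, sd: 0.3}
    nostone: {mean: 0.9, sd: 0.3}
  - name: crp_mgdl
    family: blood
    kind: continuous
    dist: lognormal
    support: [0.01, 50.0]
    stone:   {median: 0.08, q25: 0.04, q75: 0.18}
    nostone: {median: 0.10, q25: 0.03, q75: 0.35}
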