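# Royal Free Hospital score -- PROVISIONAL definition.
# The primary-source coefficients were not available when this file was
# transcribed. The input set matches the published score (log bilirubin,
# log lactate, PT ratio, urea, and the number of failing organ systems;
# see organ_failure_count() for the criteria) and the coefficients are a
# synthetic placeholder scaled so the score's distribution in an emulated
# general-ICU cirrhosis cohort matches the published magnitude (median
# near 0, IQR roughly -1 to 2). Replace with the primary-source
# coefficients before any clinical use.
name: rfh
kind: linear_predictor
intercept: -6.0
provisional: true
source: "Theocharidou et al. (RFH score); provisional synthetic coefficients"
components:
  - field: bilirubin
    transform: log
    coefficient: 0.9
    floor: 1.0
  - field: lactate
    transform: log
    coefficient: 1.4
    floor: 0.1
  - field: pt_ratio
    transform: identity
    coefficient: 0.6
  - field: urea
    transform: identity
    coefficient: 0.02
  - field: organ_failures
    transform: identity
    coefficient: 0.5
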