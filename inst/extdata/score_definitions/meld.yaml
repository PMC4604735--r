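# Model for End-stage Liver Disease (original non-rounded scale).
# Inputs floored at 1.0 before the natural log; creatinine capped at
# 4.0 mg/dL per the standard definition.
name: meld
kind: linear_predictor
intercept: 6.43
source: "Kamath et al., Hepatology 2001 (MELD); UNOS input clamps"
components:
  - field: bilirubin_mgdl
    transform: log
    coefficient: 3.78
    floor: 1.0
  - field: pt_ratio
    transform: log
    coefficient: 11.2
    floor: 1.0
  - field: creatinine_mgdl
    transform: log
    coefficient: 9.57
    floor: 1.0
    cap: 4.0
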