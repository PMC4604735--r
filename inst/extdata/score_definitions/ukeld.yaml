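# United Kingdom model for End-stage Liver Disease.
# Creatinine and bilirubin in umol/L, sodium in mmol/L, INR dimensionless.
name: ukeld
kind: linear_predictor
intercept: 435
source: "Barber et al., Transplantation 2011 (UKELD)"
components:
  - field: pt_ratio
    transform: log
    coefficient: 5.395
    floor: 1.0
  - field: creatinine
    transform: log
    coefficient: 1.485
    floor: 1.0
  - field: bilirubin
    transform: log
    coefficient: 3.13
    floor: 1.0
  - field: sodium
    transform: log
    coefficient: -81.565
    floor: 1.0
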