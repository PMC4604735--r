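# Sequential Organ Failure Assessment: six organ systems scored 0-4.
# Band edges are ascending lower bounds (left-closed, right-open bands).
# Respiratory bands are on PaO2/FiO2 in mmHg (converted from kPa);
# cardio_support is the derived vasopressor/MAP stage (0/1/3/4).
name: sofa
kind: band_sum
bounds: [0, 24]
source: "Vincent et al., Intensive Care Med 1996 (SOFA)"
components:
  - field: pf_mmhg
    edges: [100, 200, 300, 400]
    points: [4, 3, 2, 1, 0]
  - field: platelets
    edges: [20, 50, 100, 150]
    points: [4, 3, 2, 1, 0]
  - field: bilirubin
    edges: [20, 33, 102, 205]
    points: [0, 1, 2, 3, 4]
  - field: cardio_support
    edges: [1, 3, 4]
    points: [0, 1, 3, 4]
  - field: gcs
    edges: [6, 10, 13, 15]
    points: [4, 3, 2, 1, 0]
  - field: creatinine
    edges: [110, 171, 300, 440]
    points: [0, 1, 2, 3, 4]
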