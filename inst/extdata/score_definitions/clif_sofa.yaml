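# Chronic Liver Failure - SOFA: the cirrhosis modification of SOFA.
# Cerebral system is scored on the West Haven encephalopathy grade and
# coagulation on the INR/PT ratio; liver and renal bands follow the
# CLIF mg/dL cut-offs expressed in umol/L.
name: clif_sofa
kind: band_sum
bounds: [0, 24]
source: "Moreau et al., Gastroenterology 2013 (CANONIC CLIF-SOFA)"
components:
  - field: pf_mmhg
    edges: [100, 200, 300, 400]
    points: [4, 3, 2, 1, 0]
  - field: pt_ratio
    edges: [1.1, 1.25, 1.5, 2.5]
    points: [0, 1, 2, 3, 4]
  - field: bilirubin
    edges: [20, 34, 102, 205]
    points: [0, 1, 2, 3, 4]
  - field: cardio_support
    edges: [1, 3, 4]
    points: [0, 1, 3, 4]
  - field: encephalopathy
    edges: [1, 2, 3, 4]
    points: [0, 1, 2, 3, 4]
  - field: creatinine
    edges: [106, 177, 309, 442]
    points: [0, 1, 2, 3, 4]
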