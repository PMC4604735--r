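# APACHE II restricted to the admission variables in the collected set.
# First-available admission values are used rather than worst-in-24-h.
# Physiology variables not collected (temperature, heart rate, respiratory
# rate, arterial pH, haematocrit) are absent from this definition and the
# listed components score their zero-point band when missing
# (missing_points: the normal-if-missing physiology convention).
# Oxygenation is scored on PaO2 (mmHg) bands. The constant offset of 5 is
# the chronic-health adjustment: every patient in this population has
# biopsy-proven or clinically evident cirrhosis and a nonoperative
# admission. Age points are the standard APACHE II age bands.
name: apache_ii
kind: band_sum
offset: 5
source: "Knaus et al., Crit Care Med 1985 (APACHE II); restricted input set"
components:
  - field: map
    edges: [50, 70, 110, 130, 160]
    points: [4, 2, 0, 2, 3, 4]
    missing_points: 0
  - field: pao2_mmhg
    edges: [55, 61, 71]
    points: [4, 3, 1, 0]
    missing_points: 0
  - field: sodium
    edges: [111, 120, 130, 150, 155, 160, 180]
    points: [4, 3, 2, 0, 1, 2, 3, 4]
    missing_points: 0
  - field: potassium
    edges: [2.5, 3, 3.5, 5.5, 6, 7]
    points: [4, 2, 1, 0, 1, 3, 4]
    missing_points: 0
  - field: creatinine_mgdl
    edges: [0.6, 1.5, 2, 3.5]
    points: [2, 0, 2, 3, 4]
    missing_points: 0
  - field: wcc
    edges: [1, 3, 15, 20, 40]
    points: [4, 2, 0, 1, 2, 4]
    missing_points: 0
  - field: gcs_deficit
    edges: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
    points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
    missing_points: 0
  - field: age
    edges: [45, 55, 65, 75]
    points: [0, 2, 3, 5, 6]
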