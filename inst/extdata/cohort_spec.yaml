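'n':
  traditional: 78.0
  mdc: 350.0
stage_props:
  traditional:
    '1': 0.307692307692
    '2': 0.076923076923
    '3': 0.179487179487
    '4': 0.371794871795
    undetermined: 0.064102564103
  mdc:
    '1': 0.311428571429
    '2': 0.074285714286
    '3': 0.197142857143
    '4': 0.408571428571
    undetermined: 0.008571428571
diagnosis_props:
  traditional:
    NSCLC: 0.884615384615
    SCLC: 0.115384615385
    presumed_LC: 0.0
    non_LC: 0.0
  mdc:
    NSCLC: 0.742857142857
    SCLC: 0.128571428571
    presumed_LC: 0.128571428571
    non_LC: 0.0
visit_means:
  traditional:
    '1': 2.29
    '2': 2.33
    '3': 3.43
    '4': 2.55
    undetermined: 3.6
  mdc:
    '1': 1.66
    '2': 2.13
    '3': 2.03
    '4': 1.29
    undetermined: 2.333333333333
visit_max: 8.0
biopsy_mean:
  traditional: 1.32
  mdc: 1.17
imaging_mean:
  traditional: 2.24
  mdc: 2.02
distance_mean_km:
  traditional: 102.0
  mdc: 102.0
distance_sdlog: 0.6
caregiver_probs:
  '1': 0.8
  '2': 0.16
  '3': 0.03
  '4': 0.01
age_mean:
  traditional: 70.0
  mdc: 71.7
age_sd:
  traditional: 9.7
  mdc: 9.1
ebus_prob:
  traditional: 0.15
  mdc: 0.6
under65_prop:
  traditional: 0.23
  mdc: 0.225714285714
treatment_rates:
  stage:
  - '1'
  - '1'
  - '2'
  - '2'
  - '3'
  - '4'
  treatment:
  - TS
  - RT
  - TS
  - RT
  - ST;RT
  - ST
  traditional:
  - 0.208333333333
  - 0.875
  - 0.333333333333
  - 0.833333333333
  - 0.571428571429
  - 0.379310344828
  mdc:
  - 0.137614678899
  - 0.770642201835
  - 0.230769230769
  - 0.653846153846
  - 0.536231884058
  - 0.398601398601
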