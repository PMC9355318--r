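factors:
- general
- anger_aggression
- distress_avoidance
- overall_impairment
- global_impact
n_categories: 5
checksum: 352.25
items:
- item_id: 1.0
  a:
  - 1.96
  - 1.09
  - 0.0
  - 0.0
  - 0.0
  d:
  - 5.69
  - 3.46
  - 0.49
  - -2.35
- item_id: 2.0
  a:
  - 5.15
  - 5.83
  - 0.0
  - 0.0
  - 0.0
  d:
  - 6.03
  - 0.41
  - -5.7
  - -11.9
- item_id: 4.0
  a:
  - 0.82
  - 0.55
  - 0.66
  - 0.0
  - 0.0
  d:
  - 1.46
  - 0.56
  - -0.98
  - -2.66
- item_id: 5.0
  a:
  - 2.85
  - 0.0
  - 2.17
  - 0.0
  - 0.0
  d:
  - 2.09
  - 0.07
  - -2.44
  - -5.61
- item_id: 6.0
  a:
  - 2.07
  - 0.0
  - 0.97
  - 0.0
  - 0.0
  d:
  - 2.8
  - 1.16
  - -0.92
  - -2.76
- item_id: 7.0
  a:
  - 1.78
  - 1.37
  - 0.0
  - 0.0
  - 0.0
  d:
  - -0.16
  - -1.85
  - -3.48
  - -5.18
- item_id: 8.0
  a:
  - 2.24
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  d:
  - 0.65
  - -0.68
  - -2.43
  - -4.55
- item_id: 9.0
  a:
  - 2.47
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  d:
  - 3.75
  - 1.98
  - -0.34
  - -2.75
- item_id: 10.0
  a:
  - 1.32
  - 0.0
  - 0.3
  - 0.0
  - 0.0
  d:
  - 0.18
  - -0.47
  - -1.6
  - -2.91
- item_id: 12.0
  a:
  - 1.29
  - 0.0
  - 0.3
  - 0.0
  - 0.0
  d:
  - 1.39
  - -0.1
  - -1.75
  - -3.49
- item_id: 13.0
  a:
  - 2.53
  - 0.0
  - 0.0
  - 2.59
  - 0.0
  d:
  - -1.67
  - -4.96
  - -7.52
  - -9.6
- item_id: 14.0
  a:
  - 1.38
  - 0.0
  - 0.0
  - 1.7
  - 0.0
  d:
  - -0.79
  - -2.8
  - -4.61
  - -6.52
- item_id: 15.0
  a:
  - 2.12
  - 0.0
  - 0.0
  - 2.67
  - 0.0
  d:
  - -2.75
  - -4.92
  - -7.26
  - -8.83
- item_id: 16.0
  a:
  - 1.79
  - 0.0
  - 0.0
  - 2.73
  - 0.0
  d:
  - -3.36
  - -5.24
  - -6.92
  - -8.87
- item_id: 18.0
  a:
  - 3.52
  - 0.0
  - 0.0
  - 2.87
  - 1.98
  d:
  - -0.13
  - -4.35
  - -7.66
  - -10.69
- item_id: 19.0
  a:
  - 5.33
  - 0.0
  - 0.0
  - 4.28
  - 3.52
  d:
  - -0.18
  - -6.89
  - -11.19
  - -15.65
- item_id: 20.0
  a:
  - 3.35
  - 0.0
  - 0.0
  - 2.78
  - 1.84
  d:
  - -2.67
  - -6.17
  - -8.19
  - -10.46

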