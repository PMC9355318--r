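factors:
- general
- anger_aggression
- distress_avoidance
- overall_impairment
- global_impact
n_categories: 5
checksum: 262.59
items:
- item_id: 1.0
  a:
  - 1.6
  - 0.77
  - 0.0
  - 0.0
  - 0.0
  d:
  - 6.03
  - 4.48
  - 2.06
  - -0.01
- item_id: 2.0
  a:
  - 4.32
  - 5.36
  - 0.0
  - 0.0
  - 0.0
  d:
  - 7.38
  - 3.59
  - -2.27
  - -6.93
- item_id: 4.0
  a:
  - 1.0
  - 0.64
  - -0.07
  - 0.0
  - 0.0
  d:
  - 1.82
  - 0.78
  - -0.53
  - -1.97
- item_id: 5.0
  a:
  - 2.34
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  d:
  - 4.06
  - 2.8
  - 1.1
  - -0.9
- item_id: 6.0
  a:
  - 2.41
  - 0.0
  - 1.84
  - 0.0
  - 0.0
  d:
  - 6.74
  - 5.23
  - 2.64
  - 0.45
- item_id: 7.0
  a:
  - 1.55
  - 1.4
  - 0.0
  - 0.0
  - 0.0
  d:
  - 1.16
  - -0.29
  - -2.01
  - -3.39
- item_id: 8.0
  a:
  - 1.7
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  d:
  - 2.61
  - 1.29
  - -0.29
  - -1.73
- item_id: 9.0
  a:
  - 2.27
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  d:
  - 6.25
  - 4.59
  - 1.91
  - 0.03
- item_id: 10.0
  a:
  - 1.31
  - 0.0
  - 0.11
  - 0.0
  - 0.0
  d:
  - 1.73
  - 1.34
  - 0.28
  - -0.94
- item_id: 12.0
  a:
  - 1.25
  - 0.0
  - 0.25
  - 0.49
  - 0.0
  d:
  - 3.54
  - 2.21
  - 0.41
  - -1.2
- item_id: 13.0
  a:
  - 2.44
  - 0.0
  - 0.0
  - 3.25
  - 0.0
  d:
  - 2.68
  - -0.8
  - -4.67
  - -7.7
- item_id: 14.0
  a:
  - 1.43
  - 0.0
  - 0.0
  - 2.42
  - 0.0
  d:
  - 0.91
  - -1.0
  - -3.13
  - -5.14
- item_id: 15.0
  a:
  - 1.69
  - 0.0
  - 0.0
  - 2.25
  - 0.0
  d:
  - 0.75
  - -1.39
  - -3.67
  - -6.04
- item_id: 16.0
  a:
  - 1.25
  - 0.0
  - 0.0
  - 1.98
  - 0.0
  d:
  - 0.04
  - -0.98
  - -2.4
  - -3.73
- item_id: 18.0
  a:
  - 3.0
  - 0.0
  - 0.0
  - 2.55
  - 1.99
  d:
  - 5.51
  - 1.26
  - -2.82
  - -6.3
- item_id: 19.0
  a:
  - 3.57
  - 0.0
  - 0.0
  - 2.82
  - 2.74
  d:
  - 7.31
  - 1.83
  - -2.52
  - -7.34
- item_id: 20.0
  a:
  - 2.56
  - 0.0
  - 0.0
  - 1.9
  - 1.83
  d:
  - 2.85
  - -0.3
  - -3.43
  - -5.77

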