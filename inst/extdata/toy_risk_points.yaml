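# Synthetic (toy) additive risk point table for tests and examples.
# Point values are NOT from any published risk model; supply your own
# table for real use.
factors:
  age:
    breaks: [40, 50, 60, 70]
    points: [0, 1, 2, 3, 4]
  sex:
    levels:
      F: 0
      M: 1
  symptom_type:
    levels:
      noncardiac: 0
      atypical: 1
      typical: 2
  diabetes:
    levels:
      "0": 0
      "1": 1
  hypertension:
    levels:
      "0": 0
      "1": 1
  family_history:
    levels:
      "0": 0
      "1": 1
  smoking:
    levels:
      "0": 0
      "1": 1
cutpoints: [3, 6, 9]
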