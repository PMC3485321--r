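{
  "name": "ERATO_SINGLE_LOCUS",
  "description": "Single-locus null: the hindwing yellow bar is controlled by Cr alone (race-homozygotes barred, hybrids fuzzy). Rejected by the favorinus backcross segregation ratio.",
  "loci": ["Cr"],
  "free_parameter_count": 0,
  "rules": [
    {"when": {"Cr": "hom_same_race"}, "then": {"YELLOW_BAR": 1}},
    {"when": {}, "then": {"FUZZY_BAR": 1}}
  ]
}
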