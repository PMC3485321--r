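{
  "name": "ERATO_UNIFIED_MODIFIER",
  "description": "ERATO_UNIFIED plus a penetrance parameter: Cr-hybrid individuals that would be fuzzy-barred turn black-hindwing with probability p_black (the speculative unidentified third locus encoded as penetrance).",
  "loci": ["Cr", "Sd"],
  "free_parameter_count": 1,
  "params": {"p_black": 0.5},
  "rules": [
    {"when": {"Cr": "hom_same_race"}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Cr": "hybrid", "Sd": {"hom_race": "fav"}}, "then": {"YELLOW_BAR": 1}},
    {"when": {}, "then": {"FUZZY_BAR": "1 - p_black", "BLACK_HINDWING": "p_black"}}
  ],
  "observed": [
    {"Cr": {"hom_race": "pet"}, "Sd": {"hom_race": "pet"}},
    {"Cr": {"hom_race": "pet"}, "Sd": "hybrid"},
    {"Cr": "hybrid", "Sd": {"hom_race": "pet"}},
    {"Cr": "hybrid", "Sd": "hybrid"},
    {"Cr": "hybrid", "Sd": {"hom_race": "fav"}},
    {"Cr": {"hom_race": "fav"}, "Sd": "hybrid"},
    {"Cr": {"hom_race": "fav"}, "Sd": {"hom_race": "fav"}}
  ]
}
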