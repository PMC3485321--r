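{
  "name": "ERATO_UNIFIED",
  "description": "Two-locus epistatic control of the H. erato hindwing yellow bar: a full bar requires race-homozygosity at Cr or a fav/fav genotype at Sd; Cr-hybrids otherwise show the F1-like fuzzy bar.",
  "loci": ["Cr", "Sd"],
  "free_parameter_count": 0,
  "rules": [
    {"when": {"Cr": "hom_same_race"}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Cr": "hybrid", "Sd": {"hom_race": "fav"}}, "then": {"YELLOW_BAR": 1}},
    {"when": {}, "then": {"FUZZY_BAR": 1}}
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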