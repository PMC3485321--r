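{
  "name": "ERATO_MODIFIER_LOCUS",
  "description": "Alternative encoding of the black-hindwing effect as an explicit unlinked biallelic modifier locus Mod: Cr-hybrids carrying the pet.b modifier allele are black-hindwing. With a heterozygous b/+ backcross parent this reproduces the penetrance-0.5 expectations of ERATO_UNIFIED_MODIFIER exactly.",
  "loci": ["Cr", "Sd", "Mod"],
  "free_parameter_count": 0,
  "rules": [
    {"when": {"Cr": "hom_same_race"}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Cr": "hybrid", "Sd": {"hom_race": "fav"}}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Cr": "hybrid", "Mod": {"any_in": ["pet.b"]}}, "then": {"BLACK_HINDWING": 1}},
    {"when": {}, "then": {"FUZZY_BAR": 1}}
  ]
}
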