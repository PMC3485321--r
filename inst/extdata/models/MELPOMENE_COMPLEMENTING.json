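{
  "name": "MELPOMENE_COMPLEMENTING",
  "description": "Failure to complement between H. m. rosina and H. m. amaryllis: their yb alleles are interchangeable, so every genotype drawn from the two races carries the full yellow bar; a dominant Yb allele, if introduced, would shadow the bar.",
  "loci": ["Yb"],
  "free_parameter_count": 0,
  "rules": [
    {"when": {"Yb": {"both_in": ["ros", "ama"]}}, "then": {"YELLOW_BAR": 1}},
    {"when": {}, "then": {"SHADOW_BAR": 1}}
  ]
}
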