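{
  "name": "MELPOMENE_YB",
  "description": "Classical co-dominant control at the H. melpomene Yb locus: yb/yb (two bar alleles, races ros/ama) gives the yellow bar, Yb/yb heterozygotes the unpigmented shadow bar, Yb/Yb the black hindwing.",
  "loci": ["Yb"],
  "free_parameter_count": 0,
  "rules": [
    {"when": {"Yb": {"both_in": ["ros", "ama"]}}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Yb": {"none_in": ["ros", "ama"]}}, "then": {"BLACK_HINDWING": 1}},
    {"when": {}, "then": {"SHADOW_BAR": 1}}
  ]
}
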