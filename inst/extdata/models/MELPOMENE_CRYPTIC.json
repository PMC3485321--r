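{
  "name": "MELPOMENE_CRYPTIC",
  "description": "Cryptic standing variation at Yb in the melpomene father (a1/a2): paternal allele a1 behaves as a bar allele (pigmented bar, fuzzy/full sub-variants at 0.5/0.5), a2 as a classical Yb allele (shadow bar in heterozygotes).",
  "loci": ["Yb"],
  "free_parameter_count": 1,
  "rules": [
    {"when": {"Yb": {"both_in": ["ros", "ama"]}}, "then": {"YELLOW_BAR": 1}},
    {"when": {"Yb": {"any_in": ["mel.a1"]}}, "then": {"YELLOW_BAR": 1},
     "subvariant": {"fuzzy": 0.5, "full": 0.5}},
    {"when": {"Yb": {"any_in": ["ros", "ama"]}}, "then": {"SHADOW_BAR": 1}},
    {"when": {}, "then": {"BLACK_HINDWING": 1}}
  ],
  "observed": [
    {"Yb": {"allele_pair": ["ros", "mel.a1"]}},
    {"Yb": {"allele_pair": ["ros", "mel.a2"]}}
  ]
}
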