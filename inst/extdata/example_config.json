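{
  "seed": 1,
  "sig_figs": 2,
  "flags": {"truncate": false, "search_revcomp": true},
  "paths": {}
}
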