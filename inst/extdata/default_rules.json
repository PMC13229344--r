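{
  "rules": [
    {"id": "exactly-one-head"},
    {"id": "no-minor-alone", "minor_age": 18},
    {"id": "parent-older-than-child"},
    {"id": "min-head-age", "min_head_age": 16}
  ]
}
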