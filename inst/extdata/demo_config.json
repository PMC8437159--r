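{
  "synthetic": true,
  "outcomes": ["dds"],
  "scopes": ["combined"],
  "alpha": 0.2,
  "cluster": "site",
  "out_dir": "dietshock_demo",
  "seed": 42,
  "log_level": "info"
}
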