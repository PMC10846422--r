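{
  "title": "pdtsim treatment summary",
  "type": "object",
  "required": [
    "pct_gbm_remaining",
    "pct_gbm_killed",
    "max_T",
    "damage",
    "total_time_min",
    "energy_J",
    "energy_ledger",
    "n_packets",
    "seed",
    "config_hash"
  ],
  "properties": {
    "pct_gbm_remaining": {"type": "number", "minimum": 0, "maximum": 100},
    "pct_gbm_killed": {"type": "number", "minimum": 0, "maximum": 100},
    "total_time_min": {"type": "number", "minimum": 0},
    "energy_J": {"type": "number", "minimum": 0},
    "n_packets": {"type": "number", "minimum": 1},
    "config_hash": {"type": "string"}
  }
}
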