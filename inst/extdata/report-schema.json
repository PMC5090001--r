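{
  "title": "spikebench benchmark report",
  "required": {
    "description": ["input", "network", "training", "recognition"],
    "metrics": ["accuracy_pct", "n_trials", "sopbs", "input_rate_hz"]
  },
  "optional": {
    "metrics": ["latency_mean_ms", "latency_sd_ms", "latency_excluded",
                "latency_mean_all_ms", "n_no_decision", "energy"]
  }
}
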