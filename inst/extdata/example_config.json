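{
  "scenario": "all_suture",
  "setting": "hospital",
  "start_age": 35,
  "wtp_threshold": 100000,
  "failure_window_years": 3
}
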