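{
  "scale": "BPS",
  "response_range": [1, 7],
  "subscales": {
    "boredom_proneness": ["bps01", "bps02", "bps03", "bps04", "bps05", "bps06", "bps07", "bps08", "bps09", "bps10", "bps11", "bps12", "bps13", "bps14", "bps15", "bps16", "bps17", "bps18", "bps19", "bps20", "bps21", "bps22", "bps23", "bps24", "bps25", "bps26", "bps27", "bps28"]
  },
  "reverse_items": [],
  "notes": "Boredom Proneness Scale, 28 items on 1-7 (sum range 28-196). Reverse-coded item set left empty here: it varies by translation, so edit this key to match the administered version."
}
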