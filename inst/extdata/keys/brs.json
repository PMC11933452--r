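{
  "scale": "BRS",
  "response_range": [1, 5],
  "subscales": {
    "resilience": ["brs01", "brs02", "brs03", "brs04", "brs05", "brs06"]
  },
  "reverse_items": ["brs02", "brs04", "brs06"],
  "notes": "Brief Resilience Scale, 6 items on 1-5; even items reverse-coded; sum range 6-30."
}
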