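{
  "scale": "MSBS",
  "response_range": [1, 7],
  "subscales": {
    "state_boredom": ["msbs01", "msbs02", "msbs03", "msbs04", "msbs05", "msbs06", "msbs07", "msbs08"]
  },
  "reverse_items": [],
  "notes": "Multidimensional State Boredom Scale short form, 8 items on 1-7 (sum range 8-56)."
}
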