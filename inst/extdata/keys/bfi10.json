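{
  "scale": "BFI-10",
  "response_range": [1, 5],
  "subscales": {
    "extraversion": ["bfi01", "bfi06"],
    "agreeableness": ["bfi02", "bfi07"],
    "conscientiousness": ["bfi03", "bfi08"],
    "neuroticism": ["bfi04", "bfi09"],
    "openness": ["bfi05", "bfi10"]
  },
  "reverse_items": ["bfi01", "bfi03", "bfi04", "bfi05", "bfi07"],
  "notes": "Published 10-item Big Five short-form scoring; each dimension is the sum of two 1-5 items (range 2-10)."
}
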