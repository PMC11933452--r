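{
  "scale": "STAI-Y",
  "response_range": [1, 4],
  "subscales": {
    "trait_anxiety": ["stai01", "stai02", "stai03", "stai04", "stai05", "stai06", "stai07", "stai08", "stai09", "stai10", "stai11", "stai12", "stai13", "stai14", "stai15", "stai16", "stai17", "stai18", "stai19", "stai20"]
  },
  "reverse_items": ["stai01", "stai03", "stai06", "stai07", "stai10", "stai13", "stai14", "stai16", "stai19"],
  "notes": "State-Trait Anxiety Inventory, trait form: 20 items on 1-4 (sum range 20-80); anxiety-absent items reverse-coded."
}
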