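{
  "title": "bioheatr run manifest",
  "type": "object",
  "required": ["package", "version", "scenario", "samples", "duration_s", "invariants"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "scenario": {"type": "string"},
    "samples": {"type": "number"},
    "duration_s": {"type": "number"},
    "invariants": {"type": "object"}
  }
}
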