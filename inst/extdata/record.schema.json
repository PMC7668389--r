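{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "PPG record annotation sidecar",
  "type": "object",
  "required": ["fs", "n_samples", "onsets", "beats", "meta"],
  "properties": {
    "fs": {"type": "number", "exclusiveMinimum": 0},
    "n_samples": {"type": "integer", "minimum": 1},
    "onsets": {
      "type": "array",
      "items": {"type": "integer", "minimum": 0},
      "description": "0-based sample indices of beat starts, strictly increasing, first element 0"
    },
    "beats": {
      "type": "object",
      "required": ["duration_ms", "role", "group_type"],
      "properties": {
        "duration_ms": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}},
        "role": {"type": "array", "items": {"enum": ["reference", "first", "second"]}},
        "group_type": {"type": "array", "items": {"enum": ["none", "compensation", "reset", "interpolation"]}}
      }
    },
    "meta": {
      "type": "object",
      "properties": {
        "signal_type": {"enum": ["regular", "compensation", "reset", "interpolation"]},
        "length_s": {"type": "number"},
        "smoothed": {"type": "boolean"},
        "config": {"type": "object"},
        "version": {"type": "string"}
      }
    }
  }
}
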