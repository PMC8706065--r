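{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "vorx session report",
  "description": "Summary of one VORx1 exercise session. Angles in degrees, times in seconds, tempi in beats per minute, percentages in [0,100].",
  "type": "object",
  "required": ["timestamp", "complete", "prescription", "head_speed", "gaze", "coins", "symptoms"],
  "properties": {
    "timestamp": { "type": "string" },
    "complete": { "type": "boolean" },
    "prescription": {
      "type": "object",
      "required": ["direction", "goal_bpm", "duration_s", "compliance_delta_bpm"],
      "properties": {
        "direction": { "enum": ["horizontal", "vertical"] },
        "goal_bpm": { "type": "number", "exclusiveMinimum": 0 },
        "duration_s": { "type": "number", "exclusiveMinimum": 0 },
        "compliance_delta_bpm": { "type": "number", "minimum": 0 }
      }
    },
    "head_speed": {
      "type": "object",
      "required": ["n_peaks", "n_valleys", "n_intervals"],
      "properties": {
        "percent_correct": { "type": "number", "minimum": 0, "maximum": 100 },
        "mean_bpm": { "type": "number" },
        "n_peaks": { "type": "integer", "minimum": 0 },
        "n_valleys": { "type": "integer", "minimum": 0 },
        "n_intervals": { "type": "integer", "minimum": 0 }
      }
    },
    "gaze": {
      "type": "object",
      "properties": {
        "percent_on_target": { "type": "number", "minimum": 0, "maximum": 100 }
      }
    },
    "coins": { "type": "integer", "minimum": 0, "maximum": 15 },
    "symptoms": {
      "type": "object",
      "required": ["pre"],
      "properties": {
        "pre": { "$ref": "#/$defs/ratings" },
        "post": { "$ref": "#/$defs/ratings" },
        "delta": { "type": "object" }
      }
    },
    "difficulty": { "type": "integer", "minimum": 0, "maximum": 10 }
  },
  "$defs": {
    "ratings": {
      "type": "object",
      "required": ["dizziness", "headache", "nausea", "fogginess"],
      "properties": {
        "dizziness": { "type": "number", "minimum": 0, "maximum": 10 },
        "headache": { "type": "number", "minimum": 0, "maximum": 10 },
        "nausea": { "type": "number", "minimum": 0, "maximum": 10 },
        "fogginess": { "type": "number", "minimum": 0, "maximum": 10 }
      }
    }
  }
}
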