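{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "exerkin trial recording",
  "description": "One exergame trial: 33-landmark 3D world-coordinate trajectory (meters, right-handed, y-up) plus the game event log. One trial per file, UTF-8.",
  "type": "object",
  "required": ["meta", "landmarks", "events"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["subject_id", "exergame", "level", "session_index", "completed", "nominal_fps"],
      "properties": {
        "subject_id": {"type": "string"},
        "exergame": {"enum": ["AIRPLANE", "SKI", "PIANO", "GYM_FRONTAL", "GYM_LATERAL"]},
        "level": {"type": "integer", "minimum": 0},
        "session_index": {"type": "integer", "minimum": 1, "maximum": 10},
        "mode": {"enum": ["SING", "ALT", "SIM", null]},
        "completed": {"type": "boolean"},
        "nominal_fps": {"type": "number", "exclusiveMinimum": 0},
        "landmark_names": {"type": "array", "items": {"type": "string"}, "minItems": 33, "maxItems": 33}
      }
    },
    "landmarks": {
      "type": "array",
      "minItems": 1,
      "description": "Frames in strictly increasing time order.",
      "items": {
        "type": "object",
        "required": ["t", "xyz"],
        "properties": {
          "t": {"type": "number"},
          "xyz": {
            "type": "array",
            "minItems": 33,
            "maxItems": 33,
            "items": {
              "type": "array",
              "minItems": 3,
              "maxItems": 3,
              "items": {"type": ["number", "null"]}
            }
          }
        }
      }
    },
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["kind", "t"],
        "properties": {
          "kind": {"enum": ["point", "error", "pause_start", "pause_end", "key_press", "movement_valid", "movement_invalid", "level_complete", "abort"]},
          "t": {"type": "number"},
          "payload": {"type": "object"}
        }
      }
    }
  }
}
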