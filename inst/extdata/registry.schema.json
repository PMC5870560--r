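{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dynatrack registry configuration",
  "type": "object",
  "properties": {
    "global_max_visible": {
      "type": "integer",
      "minimum": 1,
      "description": "Global cap on group-managed visible tracks; absent = unlimited. Static tracks never count against it."
    },
    "static_tracks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "path", "position"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "path": {"type": "string", "minLength": 1},
          "position": {"type": "integer", "minimum": 0}
        },
        "additionalProperties": false
      }
    },
    "groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "mode": {"enum": ["automatic", "manual", "disabled"], "default": "automatic"},
          "anchor": {
            "type": "string",
            "description": "Id of a static track or another group; the anchor relation must be acyclic."
          },
          "max_visible": {"type": "integer", "minimum": 1}
        },
        "additionalProperties": false
      }
    },
    "track_sets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "signal_path", "feature_path", "group_id", "rank"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "signal_path": {"type": "string", "minLength": 1},
          "feature_path": {"type": "string", "minLength": 1},
          "group_id": {"type": "string", "minLength": 1},
          "rank": {"type": "integer", "minimum": 0}
        },
        "additionalProperties": false
      }
    }
  },
  "required": ["groups", "track_sets"],
  "additionalProperties": false
}
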