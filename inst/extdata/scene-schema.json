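{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "jointpart scene",
  "description": "JSON scene dialect for joint-constraint graphs. Coordinates are raw right-handed scene units; angles are degrees.",
  "type": "object",
  "required": ["schema_version", "joints"],
  "properties": {
    "schema_version": { "const": 1 },
    "joints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "pos"],
        "properties": {
          "id": { "type": "string" },
          "pos": { "$ref": "#/$defs/vec3", "description": "current position" },
          "pos0": { "$ref": "#/$defs/vec3", "description": "initial position; defaults to pos" },
          "stiffness": { "type": "number", "exclusiveMinimum": 0, "default": 1 },
          "destination": { "$ref": "#/$defs/vec3" },
          "virtual": { "type": "boolean", "default": false },
          "twin": { "type": "string", "description": "id of the duplicated real joint; required iff virtual" },
          "mesh": { "type": "string", "description": "opaque mesh reference, carried but never interpreted" }
        }
      }
    },
    "constraints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["kind", "i", "j"],
        "properties": {
          "kind": { "enum": ["A", "B", "C", "D"] },
          "i": { "type": "string" },
          "j": { "type": "string" },
          "dist": { "type": "number", "minimum": 0, "description": "rest distance (kinds A, C)" },
          "dmax": { "type": "number", "minimum": 0, "description": "max displacement (kind C)" },
          "theta": { "type": "number", "exclusiveMinimum": 0, "maximum": 180, "description": "max pivot angle in degrees (kind B)" },
          "axis": { "enum": ["x", "y", "z"], "description": "optional axis lock (kind B)" },
          "cone_angle": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 180, "description": "cone aperture in degrees (kind D)" },
          "cone_radius": { "type": "number", "minimum": 0, "description": "cone radius (kind D)" }
        }
      }
    },
    "metadata": { "type": "object" }
  },
  "$defs": {
    "vec3": {
      "type": "array",
      "items": { "type": "number" },
      "minItems": 3,
      "maxItems": 3
    }
  }
}
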