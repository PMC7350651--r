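{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "isotrace workspace",
  "description": "Saved analysis workspace: fragments, per-fragment isotopologue matrices, sample groups, tracer, normalization state and display settings. Matrices are stored row-major with explicit row/column names.",
  "type": "object",
  "required": ["schema_version", "corrected", "samples", "fragments", "values", "abundance", "groups", "settings"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "abundance_table_version": { "type": "string" },
    "corrected": { "type": "boolean" },
    "tracer": {
      "type": ["object", "null"],
      "properties": {
        "element": { "type": "string" },
        "shift": { "type": "integer", "minimum": 1 }
      }
    },
    "samples": { "type": "array", "items": { "type": "string" } },
    "fragments": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": { "type": "string" },
          "metabolite": { "type": "string" },
          "bigg_id": { "type": "string" },
          "formula": { "type": ["string", "null"] },
          "n_labelable": { "type": ["integer", "null"], "minimum": 0 }
        }
      }
    },
    "values": { "type": "object", "additionalProperties": { "$ref": "#/definitions/matrix" } },
    "abundance": { "$ref": "#/definitions/matrix" },
    "scales": { "oneOf": [{ "$ref": "#/definitions/matrix" }, { "type": "null" }] },
    "norm_abundance": { "oneOf": [{ "$ref": "#/definitions/matrix" }, { "type": "null" }] },
    "normalization": {
      "type": ["object", "null"],
      "properties": {
        "steps": { "type": "array", "items": { "enum": ["internal_standard", "cell_counts", "reference_group"] } },
        "internal_standard": { "type": ["string", "null"] },
        "cell_counts": { "type": ["object", "null"], "additionalProperties": { "type": "number" } },
        "reference_group": { "type": ["string", "null"] },
        "standards": { "type": ["array", "null"] }
      }
    },
    "excluded_samples": { "type": "array", "items": { "type": "string" } },
    "groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "samples"],
        "properties": {
          "name": { "type": "string" },
          "samples": { "type": "array", "items": { "type": "string" } },
          "time": { "type": ["number", "null"] },
          "cell_count": { "type": ["number", "null"], "exclusiveMinimum": 0 },
          "color": { "type": ["string", "null"] }
        }
      }
    },
    "settings": {
      "type": "object",
      "properties": {
        "metabolites_to_display": { "type": ["array", "null"], "items": { "type": "string" } },
        "isotopologue_limits": { "type": "object", "additionalProperties": { "type": "integer", "minimum": 1 } },
        "color_scheme": { "type": "string" }
      }
    }
  },
  "definitions": {
    "matrix": {
      "type": "object",
      "required": ["rownames", "colnames", "data"],
      "properties": {
        "rownames": { "type": "array", "items": { "type": "string" } },
        "colnames": { "type": "array", "items": { "type": "string" } },
        "data": { "type": "array", "items": { "type": "array", "items": { "type": "number" } } }
      }
    }
  }
}
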