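{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Ranked compound-disease association result",
  "description": "Ordered array of disease clusters; order encodes the ranking (descending score, lexicographic tie-break on disease).",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["disease", "score", "paths"],
    "additionalProperties": false,
    "properties": {
      "disease": { "type": "string" },
      "score": { "type": "number", "minimum": 0 },
      "paths": {
        "type": "array",
        "minItems": 1,
        "items": {
          "type": "object",
          "required": ["rule", "similar_compound", "provenance"],
          "additionalProperties": false,
          "properties": {
            "rule": { "type": "string" },
            "similar_compound": { "type": "string" },
            "similarity": { "type": "string" },
            "gene": { "type": "string" },
            "bioassay": { "type": "string" },
            "article": { "type": "string" },
            "provenance": { "type": "array", "items": { "type": "string" } }
          }
        }
      }
    }
  }
}
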