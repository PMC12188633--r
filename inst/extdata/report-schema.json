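{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "specmatch identification report",
  "type": "object",
  "required": ["query", "n_entries", "parameters", "note", "results"],
  "properties": {
    "query": { "type": "string", "description": "path of the query spectrum" },
    "n_entries": { "type": "integer", "description": "library size" },
    "threshold": {
      "type": ["number", "null"],
      "description": "background-removal intensity threshold, when cleaning ran"
    },
    "parameters": {
      "type": "object",
      "description": "run configuration used to produce the report",
      "required": ["window", "sigma", "clean", "q", "p", "c", "top"],
      "properties": {
        "window": { "enum": ["gaussian", "rectangular"] },
        "sigma": { "type": "number", "exclusiveMinimum": 0 },
        "clean": { "type": "boolean" },
        "q": { "type": "number", "minimum": 1 },
        "p": { "type": "integer", "minimum": 1 },
        "c": { "type": "number", "exclusiveMinimum": 0 },
        "top": { "type": "integer", "minimum": 1 }
      }
    },
    "note": { "type": "string" },
    "results": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rank", "id", "class", "formula", "name", "n_matched",
                     "p_matched", "total", "d_kl", "d_b", "d_h", "d_c",
                     "d_meta"],
        "properties": {
          "rank": { "type": "integer", "minimum": 1 },
          "id": { "type": "string" },
          "class": { "type": "string" },
          "formula": { "type": "string" },
          "name": { "type": "string" },
          "n_matched": { "type": "integer", "minimum": 0 },
          "p_matched": { "type": "number", "minimum": 0, "maximum": 1 },
          "total": { "type": "number", "minimum": 0 },
          "d_kl": { "type": ["number", "null"] },
          "d_b": { "type": ["number", "null"] },
          "d_h": { "type": ["number", "null"] },
          "d_c": { "type": ["number", "null"] },
          "d_meta": { "type": ["number", "string", "null"] }
        }
      }
    }
  }
}
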