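{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "snnweaver connectome import dialect",
  "description": "Connectomic data arrive as two JSON arrays: nodes (mapped to neural populations) and edges (mapped to projections). Extra keys are preserved as pass-through annotations.",
  "definitions": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": {"type": "string"},
          "number": {"type": "number", "exclusiveMinimum": 0},
          "regime": {"enum": ["excitatory", "inhibitory"]}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target"],
        "properties": {
          "source": {"type": "string"},
          "target": {"type": "string"},
          "delay": {"type": "number", "exclusiveMinimum": 0},
          "weight": {"type": "number"}
        }
      }
    }
  }
}
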