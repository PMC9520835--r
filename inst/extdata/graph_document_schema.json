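{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "kgbuildr/graph_document_schema.json",
  "title": "graph_document",
  "description": "Serialized knowledge-graph document: a JSON object with keys 'nodes' and 'edges' (plus 'build_info'). Multivalued fields are arrays of strings; canonicalized graphs add all_categories, equivalent_identifiers and all_names to nodes.",
  "type": "object",
  "required": ["nodes", "edges"],
  "additionalProperties": false,
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "category", "iri", "description",
                     "provided_by", "publications"],
        "properties": {
          "id": {"type": "string", "pattern": "^[^:]+:.+$"},
          "name": {"type": "string"},
          "category": {"type": "string"},
          "iri": {"type": "string"},
          "description": {"type": "string"},
          "provided_by": {"type": "array", "items": {"type": "string"}},
          "publications": {"type": "array", "items": {"type": "string"}},
          "all_categories": {"type": "array", "items": {"type": "string"}},
          "equivalent_identifiers": {"type": "array", "items": {"type": "string"}},
          "all_names": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subject", "predicate", "object", "relation",
                     "provided_by", "publications"],
        "properties": {
          "subject": {"type": "string", "pattern": "^[^:]+:.+$"},
          "predicate": {"type": "string"},
          "object": {"type": "string", "pattern": "^[^:]+:.+$"},
          "relation": {"type": "array", "items": {"type": "string"}},
          "provided_by": {"type": "array", "items": {"type": "string"}},
          "publications": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "build_info": {
      "type": "object",
      "description": "Model version, per-source versions, build timestamp and stage name."
    }
  }
}
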