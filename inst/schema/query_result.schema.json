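{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Coexpression query result",
  "oneOf": [
    {
      "type": "object",
      "required": ["query", "driver", "clade"],
      "properties": {
        "query": {
          "type": "object",
          "required": ["driver", "internal_nodes"],
          "properties": {
            "driver": {"type": "string"},
            "internal_nodes": {"type": "integer", "minimum": 1},
            "category": {"type": ["string", "null"]}
          }
        },
        "driver": {
          "type": "object",
          "required": ["gene_id"],
          "properties": {
            "gene_id": {"type": "string"},
            "description": {"type": ["string", "null"]}
          }
        },
        "clade": {
          "type": "object",
          "required": ["internal_nodes", "capped", "size", "newick", "genes"],
          "properties": {
            "internal_nodes": {"type": "integer", "minimum": 1},
            "requested_nodes": {"type": "integer", "minimum": 1},
            "capped": {"type": "boolean"},
            "size": {"type": "integer", "minimum": 2},
            "newick": {"type": "string"},
            "genes": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["gene_id"],
                "properties": {
                  "gene_id": {"type": "string"},
                  "description": {"type": ["string", "null"]}
                }
              }
            }
          }
        },
        "enrichment": {
          "type": "object",
          "required": ["category", "n_tested", "terms"],
          "properties": {
            "category": {"type": "string"},
            "n_tested": {"type": "integer", "minimum": 0},
            "terms": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["term_id", "p", "p_adj", "k", "n", "K", "N",
                             "expected", "over_representation",
                             "hit_percent"],
                "properties": {
                  "term_id": {"type": "string"},
                  "description": {"type": "string"},
                  "p": {"type": "number", "minimum": 0, "maximum": 1},
                  "p_adj": {"type": "number", "minimum": 0, "maximum": 1},
                  "k": {"type": "integer", "minimum": 1},
                  "n": {"type": "integer", "minimum": 1},
                  "K": {"type": "integer", "minimum": 1},
                  "N": {"type": "integer", "minimum": 1},
                  "expected": {"type": "number", "minimum": 0},
                  "over_representation": {"type": "number", "minimum": 0},
                  "hit_percent": {"type": "number", "minimum": 0,
                                  "maximum": 100}
                }
              }
            }
          }
        }
      }
    },
    {
      "type": "object",
      "required": ["error"],
      "properties": {
        "error": {
          "type": "object",
          "required": ["code", "message"],
          "properties": {
            "code": {"type": "string"},
            "message": {"type": "string"},
            "near_matches": {"type": "array", "items": {"type": "string"}}
          }
        }
      }
    }
  ]
}
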