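{
  "$comment": "Viewer graph dialect: Cytoscape-style elements list plus a style section.",
  "type": "object",
  "required": ["elements", "style"],
  "properties": {
    "elements": {
      "type": "object",
      "required": ["nodes", "edges"],
      "properties": {
        "nodes": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["data", "position"],
            "properties": {
              "data": {
                "type": "object",
                "required": ["id", "label", "kind", "ref"],
                "properties": {
                  "id": {"type": "string"},
                  "label": {"type": "string"},
                  "kind": {
                    "type": "string",
                    "enum": ["metabolite-node", "enzyme-label", "gene-label",
                             "pathway-label", "pathway-box", "omics-grid",
                             "omics-box"]
                  },
                  "ref": {"type": "string"}
                }
              },
              "position": {
                "type": "object",
                "required": ["x", "y"],
                "properties": {
                  "x": {"type": "number"},
                  "y": {"type": "number"}
                }
              }
            }
          }
        },
        "edges": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["data"],
            "properties": {
              "data": {
                "type": "object",
                "required": ["id", "source", "target", "kind"],
                "properties": {
                  "id": {"type": "string"},
                  "source": {"type": "string"},
                  "target": {"type": "string"},
                  "kind": {"type": "string", "enum": ["reaction", "connection"]}
                }
              }
            }
          }
        }
      }
    },
    "style": {"type": "object"}
  }
}
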