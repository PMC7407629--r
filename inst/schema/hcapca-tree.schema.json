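{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "hcapca-tree.schema.json",
  "title": "hcapca tree-of-trees export",
  "type": "object",
  "required": ["format", "format_version", "config", "root", "nodes"],
  "properties": {
    "format": {"const": "hcapca-tree"},
    "format_version": {"type": "integer", "minimum": 1},
    "config": {
      "type": "object",
      "required": ["cutoff", "metric", "min_split_size"],
      "properties": {
        "cutoff": {"type": "number", "exclusiveMinimum": 0, "maximum": 100},
        "metric": {"enum": ["euclidean", "correlation"]},
        "min_split_size": {"type": "integer", "minimum": 2}
      }
    },
    "root": {"type": "string"},
    "nodes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "children", "members", "size", "terminal"],
        "properties": {
          "name": {"type": "string"},
          "parent": {"type": ["string", "null"]},
          "children": {
            "type": "array",
            "items": {"type": "string"},
            "minItems": 0,
            "maxItems": 2
          },
          "members": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "size": {"type": "integer", "minimum": 1},
          "sov12": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "terminal": {"type": "boolean"},
          "dendrogram": {
            "type": ["object", "null"],
            "required": ["labels", "merge", "height"],
            "properties": {
              "labels": {"type": "array", "items": {"type": "string"}},
              "merge": {
                "type": "array",
                "items": {
                  "type": "array",
                  "items": {"type": "integer"},
                  "minItems": 2,
                  "maxItems": 2
                }
              },
              "height": {"type": "array", "items": {"type": "number", "minimum": 0}}
            }
          },
          "pca": {
            "type": "object",
            "required": ["explained"],
            "properties": {
              "explained": {
                "type": "array",
                "items": {"type": "number", "minimum": 0, "maximum": 1}
              },
              "files": {
                "type": "object",
                "properties": {
                  "scores": {"type": "string"},
                  "loadings": {"type": "string"}
                }
              }
            }
          }
        }
      }
    }
  }
}
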