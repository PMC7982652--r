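{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "PGDB-lite",
  "description": "Exchange format for annotated genome databases: replicons, genes, proteins, complexes, reactions, GO annotations with evidence codes, and propagation history records. Collections are arrays sorted by id; optional fields are omitted when empty, never null. Coordinates are 1-based inclusive.",
  "type": "object",
  "required": ["id", "replicons", "genes", "proteins"],
  "properties": {
    "id": {"type": "string"},
    "provenance": {"type": "object", "additionalProperties": true},
    "replicons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "topology", "gene_order"],
        "properties": {
          "id": {"type": "string"},
          "topology": {"enum": ["circular", "linear"]},
          "gene_order": {
            "type": "array", "items": {"type": "string"}, "uniqueItems": true,
            "description": "Gene ids ordered by start coordinate (ties by end, then id); defines adjacency for the synteny test."
          }
        }
      }
    },
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "replicon", "start", "end", "strand"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "synonyms": {"type": "array", "items": {"type": "string"}},
          "replicon": {"type": "string"},
          "start": {"type": "integer", "minimum": 1},
          "end": {"type": "integer", "minimum": 1},
          "strand": {"enum": ["+", "-"]},
          "product": {"type": "string", "description": "Protein id; absent for RNA genes."},
          "evidence": {"type": "array", "items": {"type": "string"}},
          "propagated_from": {"type": "string", "description": "Source gene id recorded when this gene received propagated data."}
        }
      }
    },
    "proteins": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "gene", "sequence"],
        "properties": {
          "id": {"type": "string"},
          "gene": {"type": "string"},
          "sequence": {"type": "string", "pattern": "^[ACDEFGHIKLMNPQRSTVWYX]+$"},
          "name": {"type": "string"},
          "synonyms": {"type": "array", "items": {"type": "string"}},
          "go_annotations": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["term", "evidence_code"],
              "properties": {
                "term": {"type": "string", "pattern": "^GO:[0-9]{7}$"},
                "evidence_code": {"type": "string"},
                "with_ref": {"type": "string", "description": "Supporting object; for ISO annotations, the source ortholog protein id."}
              }
            }
          },
          "reactions": {"type": "array", "items": {"type": "string"}},
          "evidence": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "complexes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "components"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "components": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["ref", "coefficient"],
              "properties": {
                "ref": {"type": "string", "description": "Protein id, sub-complex id, or gene id (RNA component)."},
                "coefficient": {"type": "integer", "minimum": 1}
              }
            }
          },
          "reactions": {"type": "array", "items": {"type": "string"}},
          "evidence": {"type": "array", "items": {"type": "string"}},
          "heteromultimeric": {"type": "boolean", "description": "Derived: >= 2 distinct flattened component species; recomputed on read."},
          "contains_rna": {"type": "boolean", "description": "Derived: some flattened component is a gene without a protein product; recomputed on read."}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "ec_number": {"type": "string"},
          "name": {"type": "string"}
        }
      }
    },
    "propagation_records": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["target_gene", "source_gene", "changed_fields", "prior_values", "timestamp"],
        "properties": {
          "target_gene": {"type": "string"},
          "source_gene": {"type": "string"},
          "changed_fields": {
            "type": "array",
            "items": {"enum": ["gene_name", "gene_synonyms", "product_name", "product_synonyms", "go_terms", "reactions", "complex_membership"]}
          },
          "prior_values": {"type": "object", "description": "Keyed exactly by changed_fields; scalar fields map to strings, set-valued fields to string arrays."},
          "timestamp": {"type": "string"}
        }
      }
    }
  }
}
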