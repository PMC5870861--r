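{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/spec2isa/file-metadata.schema.json",
  "title": "spec2isa canonical per-file metadata export",
  "type": "object",
  "required": ["source_file", "technology", "entries", "warnings"],
  "additionalProperties": false,
  "properties": {
    "source_file": { "type": "string" },
    "technology": { "enum": ["mzML", "imzML", "nmrML"] },
    "entries": {
      "type": "object",
      "description": "Keyed by term key in ruleset order; absent key means the term was not captured. Values are arrays in document order (multi-valued keys keep their structure).",
      "additionalProperties": {
        "type": "array",
        "minItems": 1,
        "items": {
          "type": "object",
          "required": ["term_accession", "term_label", "value",
                       "unit_accession", "unit_label", "source_file", "xml_path"],
          "additionalProperties": false,
          "properties": {
            "term_accession": { "type": "string" },
            "term_label": { "type": "string" },
            "value": { "type": "string" },
            "unit_accession": { "type": "string" },
            "unit_label": { "type": "string" },
            "source_file": { "type": "string" },
            "xml_path": { "type": "string" }
          }
        }
      }
    },
    "warnings": { "type": "array", "items": { "type": "string" } }
  }
}
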