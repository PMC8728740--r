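{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "memperturb run report",
  "type": "object",
  "required": ["software", "seed", "config", "stages"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "stages": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["status"],
        "properties": {
          "status": {"enum": ["ok", "error", "skipped"]}
        }
      }
    },
    "failed": {"type": "array", "items": {"type": "string"}}
  }
}
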