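{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Run report JSON",
  "description": "Summary written by run_experiment() alongside the CSV artifacts.",
  "type": "object",
  "properties": {
    "statistics": {"type": "object", "description": "named contrasts; each carries statistic, df, p, n"},
    "checklist": {"type": "object", "additionalProperties": {"type": "boolean"}},
    "model_selection": {
      "type": "object",
      "properties": {
        "winners": {"type": "object"},
        "win_counts": {"type": "object"},
        "pairs": {"type": "object"}
      }
    },
    "provenance": {
      "type": "object",
      "properties": {
        "experiment": {"enum": ["exp1", "exp2", "exp3"]},
        "seed": {"type": "integer"},
        "config_hash": {"type": "string", "pattern": "^[0-9a-f]{8}$"},
        "package_version": {"type": "string"}
      },
      "required": ["experiment", "seed", "config_hash"]
    }
  },
  "required": ["checklist", "provenance"]
}
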