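{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Trial table CSV dialect",
  "description": "Column contract for the trial-level CSV. Exact header order is required.",
  "type": "object",
  "properties": {
    "participant_id": {"type": "string"},
    "condition": {"enum": ["self", "agent"]},
    "phase": {"enum": ["before", "during", "after"]},
    "block_index": {"type": "integer", "minimum": 1},
    "direction": {"enum": [1, -1]},
    "feedback_level": {"enum": ["low", "medium", "high", "none"]},
    "target_x_px": {"type": ["number", "null"], "description": "null for no-target tasks"},
    "true_stop_x_px": {"type": "number"},
    "estimate_x_px": {"type": "number"},
    "sweeps": {"type": "integer", "minimum": 1},
    "reaction_time_s": {"type": ["number", "null"], "exclusiveMinimum": 0},
    "estimation_time_s": {"type": "number", "exclusiveMinimum": 0},
    "excluded": {"type": "boolean"},
    "excluded_reason": {"enum": ["", "est_time", "agent_rt", "est_time;agent_rt"]}
  },
  "required": ["participant_id", "condition", "phase", "block_index",
               "direction", "feedback_level", "target_x_px", "true_stop_x_px",
               "estimate_x_px", "sweeps", "reaction_time_s",
               "estimation_time_s", "excluded", "excluded_reason"]
}
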