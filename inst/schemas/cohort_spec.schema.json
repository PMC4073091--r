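{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Cohort specification",
  "type": "object",
  "properties": {
    "n_participants": {"type": "integer", "minimum": 2},
    "performance_sd_dist": {"type": "object", "properties": {"mean": {"type": "number", "exclusiveMinimum": 0}, "sd": {"type": "number", "minimum": 0}}},
    "self_exaggeration_dist": {"type": "object", "properties": {"mean": {"type": "number", "exclusiveMinimum": 0}, "sd": {"type": "number", "minimum": 0}}},
    "agent_prior_mode": {"enum": ["matched", "flat_with_prob"]},
    "agent_flat_prob": {"type": "number", "minimum": 0, "maximum": 1},
    "agent_match_sdlog": {"type": "number", "minimum": 0},
    "optimism_partial_rho": {"type": "number", "minimum": -1, "maximum": 1},
    "feedback_perf_sd_factor": {"type": "number", "exclusiveMinimum": 0},
    "feedback_evid_sd_factor": {"type": "number", "exclusiveMinimum": 0},
    "evidence_sd_ratio": {"type": "number", "exclusiveMinimum": 0},
    "agent_evidence_inflation": {"type": "number", "exclusiveMinimum": 0},
    "timing_outlier_prob": {"type": "number", "minimum": 0, "maximum": 1},
    "seed": {"type": "integer"}
  },
  "required": ["n_participants", "seed"]
}
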