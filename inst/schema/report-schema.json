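{
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "configHash", "config"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "timestamp": {"type": "string"},
        "seed": {"type": "integer"},
        "configHash": {"type": "string"},
        "config": {"type": "object"},
        "stageLog": {"type": "object"}
      }
    },
    "synth": {"type": "object"},
    "wham": {
      "type": "object",
      "required": ["f", "converged"],
      "properties": {"converged": {"type": "any"}}
    },
    "states": {"type": "array"},
    "dg": {"type": "array"},
    "populations": {"type": "object"},
    "decompose": {
      "type": "object",
      "required": ["labels", "total"]
    },
    "geometry": {"type": "object"},
    "ions": {"type": "object"},
    "cluster": {
      "type": "object",
      "required": ["nClusters", "populations"]
    },
    "error": {"type": "object"}
  }
}
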