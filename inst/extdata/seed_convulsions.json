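{
  "ae_name": "convulsions",
  "comment": "Mock lower-level terms assembled for demonstration; not the licensed regulatory terminology.",
  "llt_terms": ["seizure", "convulsion", "fit", "epileptic fit", "tremor",
                "twitching", "paddling", "collapse", "loss of consciousness",
                "nystagmus"],
  "pt_terms": ["convulsion"]
}
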