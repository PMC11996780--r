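{
  "ae_name": "renal insufficiency",
  "comment": "Mock lower-level terms assembled for demonstration; not the licensed regulatory terminology.",
  "llt_terms": ["renal failure", "kidney disease", "renal insufficiency",
                "azotaemia", "renal azotaemia", "polyuria", "polydipsia",
                "uraemia"],
  "pt_terms": ["renal insufficiency"]
}
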