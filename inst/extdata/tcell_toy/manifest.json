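{
  "go_terms": "go_terms.tsv",
  "proteins": "proteins.tsv",
  "metabolites": "metabolites.tsv",
  "ppi": "ppi.tsv",
  "reactions": "reactions.tsv",
  "root": "GO:0002376",
  "min_confidence": 400
}
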