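{
  "name": "author_designation",
  "fallback": "use_author_flag",
  "rules": [
    {"term": "joint sprain", "severity": "serious", "locality": "joint"},
    {"term": "cancer", "severity": "serious", "locality": "other"},
    {"term": "breast cancer", "severity": "serious", "locality": "other"},
    {"term": "myocardial infarction", "severity": "non_serious", "locality": "other"},
    {"term": "severe knee swelling", "severity": "non_serious", "locality": "joint"},
    {"term": "cerebral hemorrhage", "severity": "non_serious", "locality": "other"},
    {"term": "flare", "severity": "non_serious", "locality": "joint"}
  ]
}
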