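{
  "name": "team_judgment",
  "fallback": "use_author_flag",
  "rules": [
    {"term": "synovitis", "severity": "serious", "locality": "joint"},
    {"term": "septic arthritis", "severity": "serious", "locality": "joint"},
    {"term": "herpes zoster", "severity": "serious", "locality": "other"},
    {"term": "myocardial infarction", "severity": "serious", "locality": "other"},
    {"term": "cerebral hemorrhage", "severity": "serious", "locality": "other"},
    {"term": "gastrointestinal bleeding", "severity": "serious", "locality": "other"},
    {"term": "intestinal obstruction", "severity": "serious", "locality": "other"},
    {"term": "severe knee swelling", "severity": "serious", "locality": "joint"},
    {"term": "joint sprain", "severity": "non_serious", "locality": "joint"},
    {"term": "injection site pain", "severity": "non_serious", "locality": "joint"},
    {"term": "knee pain", "severity": "non_serious", "locality": "joint"},
    {"term": "effusion", "severity": "non_serious", "locality": "joint"},
    {"term": "erythema", "severity": "non_serious", "locality": "local_non_joint"},
    {"term": "rash", "severity": "non_serious", "locality": "local_non_joint"},
    {"term": "headache", "severity": "non_serious", "locality": "other"},
    {"term": "nausea", "severity": "non_serious", "locality": "other"},
    {"term": "flare", "severity": "non_serious", "locality": "joint"},
    {"term": "cancer", "severity": "not_an_AE", "locality": "n/a"},
    {"term": "breast cancer", "severity": "not_an_AE", "locality": "n/a"}
  ]
}
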