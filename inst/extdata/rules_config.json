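{
  "weights": {
    "1": 2.5, "2": 2.0, "3": 2.0, "4": 1.0, "5": 2.0, "6": -3.0,
    "7": 3.0, "8": 2.0, "9": 2.0, "10": 1.0, "11": 0.0,
    "12": 0.0, "13": 0.0, "14": 0.0, "15": 1.0, "16": -5.0, "17": 1.0
  },
  "tau": 2.5,
  "tolerance": 0.2,
  "cohort_alpha": 0.3,
  "cohort_cap": 2.0,
  "positive_keywords": [
    "database", "databases", "software", "tool", "tools", "package",
    "packages", "webserver", "webservers", "server", "repository",
    "repositories", "pipeline", "toolkit", "suite", "browser", "ontology"
  ],
  "negative_keywords": [
    "algorithm", "algorithms", "method", "methods", "approach",
    "approaches", "procedure", "procedures", "technique", "techniques",
    "assay", "assays", "protocol", "protocols", "gene", "genes",
    "protein", "proteins", "patients", "patient"
  ],
  "restricted_heads": [
    "program", "programs", "system", "systems", "project", "projects",
    "service", "services"
  ],
  "common_words": [
    "analysis", "cluster", "image", "model", "express", "mass", "amber",
    "spring", "basic", "prime", "cell", "gap", "match", "origin", "scale",
    "tree", "align", "profile", "measure", "impact", "pattern", "primer",
    "network", "vector", "focus", "signal", "domain", "factor", "marker",
    "anchor"
  ],
  "name_suffixes": [
    "db", "base", "bank", "tool", "tools", "viewer", "explorer", "finder",
    "aligner", "seq", "omics", "ware", "lab", "scan", "fold", "blast"
  ]
}
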