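{
  "schema_version": "1.0",
  "description": "Consensus prior set for one-year fistula remission in perianal fistulizing Crohn's disease, elicited at a UK expert workshop (11 gastroenterologists, November 2024). Placebo: Beta prior on the remission probability. Therapies: Normal priors on the log-odds ratio versus placebo.",
  "parameterization_note": "Effect-prior dispersion is stored as a variance (log_or_var). This is the reading under which the published arm-level summaries (prior means and 90% credible intervals of the remission rate) are reproduced exactly by the induced-prior transform; the accompanying narrative quantities (ESS, sd intervals) instead quote the dispersion number as a standard deviation.",
  "placebo": { "alpha": 2.16, "beta": 7.57 },
  "therapies": [
    { "id": "iv-infliximab",  "label": "IV infliximab",  "log_or_mean": 1.90, "log_or_var": 2.20 },
    { "id": "adalimumab",     "label": "Adalimumab",     "log_or_mean": 0.83, "log_or_var": 0.97 },
    { "id": "sc-infliximab",  "label": "SC infliximab",  "log_or_mean": 1.60, "log_or_var": 1.55 },
    { "id": "iv-vedolizumab", "label": "IV vedolizumab", "log_or_mean": 0.00, "log_or_var": 0.64 },
    { "id": "upadacitinib",   "label": "Upadacitinib",   "log_or_mean": 1.10, "log_or_var": 1.70 },
    { "id": "ustekinumab",    "label": "Ustekinumab",    "log_or_mean": 0.53, "log_or_var": 1.04 },
    { "id": "anti-il23",      "label": "Anti-IL-23",     "log_or_mean": 0.62, "log_or_var": 1.41 }
  ],
  "provenance": {
    "aggregation": "behavioural consensus (facilitated group discussion, equal expert weighting)",
    "endpoint": "fistula remission at one year, clinical criteria",
    "workshop_date": "2024-11-11"
  }
}
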