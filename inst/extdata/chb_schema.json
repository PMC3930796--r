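[
  {
    "name": "efficacy",
    "description": "Probability that the medicine will continue to work well for 5 years",
    "levels": ["71 %", "85 %", "92 %"],
    "higher_better": true
  },
  {
    "name": "bone_risk",
    "description": "Probability of thinning of bones after 5 years on the medicine",
    "levels": ["< 1 %", "7 %", "14 %"],
    "higher_better": false
  },
  {
    "name": "kidney_risk",
    "description": "Probability of kidney damage after 5 years on the medicine",
    "levels": ["< 1 %", "10 %", "20 %"],
    "higher_better": false
  },
  {
    "name": "patients_treated",
    "description": "Number of patients prescribed the medicine worldwide",
    "levels": ["100,000", "200,000", "400,000"],
    "higher_better": true
  },
  {
    "name": "years_market",
    "description": "Years the medicine has been approved in the US",
    "levels": ["2 years", "4 years", "6 years"],
    "higher_better": true
  },
  {
    "name": "cost",
    "description": "Monthly out-of-pocket cost, assuming at least 12 months of treatment",
    "levels": ["$0", "$50", "$100", "$150"],
    "higher_better": false
  }
]
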