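{
  "name": "neo21",
  "description": "Default 21-analyte urinary neonicotinoid panel: 10 parent compounds and 11 metabolites, each with an assigned isotope-labeled internal standard. Detection limits are shipped in both matrices: synthetic urine (method detection limits) and pooled urine (practical reporting limits), together with mean endogenous background measured in pooled-urine blanks (null = not detected). cal_range_high gives the upper end (ng/mL) of the accepted linear range.",
  "analytes": [
    {"name": "ACE",        "kind": "parent",     "parent_of": null,  "istd": "ACE-d3",             "lod_synthetic": 0.0050, "loq_synthetic": 0.016, "lod_pooled": 0.0070, "loq_pooled": 0.022, "blank_pooled": null, "cal_range_high": 25},
    {"name": "CLO",        "kind": "parent",     "parent_of": null,  "istd": "CLO-d3",             "lod_synthetic": 0.014,  "loq_synthetic": 0.045, "lod_pooled": 0.11,   "loq_pooled": 0.38,  "blank_pooled": 0.30, "cal_range_high": 25},
    {"name": "IMI",        "kind": "parent",     "parent_of": null,  "istd": "IMI-d4",             "lod_synthetic": 0.0060, "loq_synthetic": 0.020, "lod_pooled": 0.014,  "loq_pooled": 0.047, "blank_pooled": 0.02, "cal_range_high": 25},
    {"name": "THC",        "kind": "parent",     "parent_of": null,  "istd": "THC-d4",             "lod_synthetic": 0.0040, "loq_synthetic": 0.013, "lod_pooled": 0.021,  "loq_pooled": 0.069, "blank_pooled": null, "cal_range_high": 25},
    {"name": "THX",        "kind": "parent",     "parent_of": null,  "istd": "THX-d3",             "lod_synthetic": 0.0070, "loq_synthetic": 0.023, "lod_pooled": 0.032,  "loq_pooled": 0.11,  "blank_pooled": 0.07, "cal_range_high": 25},
    {"name": "NIT",        "kind": "parent",     "parent_of": null,  "istd": "NIT-d3",             "lod_synthetic": 0.0070, "loq_synthetic": 0.024, "lod_pooled": 0.025,  "loq_pooled": 0.083, "blank_pooled": null, "cal_range_high": 10},
    {"name": "FLU",        "kind": "parent",     "parent_of": null,  "istd": "ACE-d3",             "lod_synthetic": 0.0040, "loq_synthetic": 0.013, "lod_pooled": 0.032,  "loq_pooled": 0.11,  "blank_pooled": null, "cal_range_high": 25},
    {"name": "FLO",        "kind": "parent",     "parent_of": null,  "istd": "FLO-d3",             "lod_synthetic": 0.0060, "loq_synthetic": 0.020, "lod_pooled": 0.010,  "loq_pooled": 0.032, "blank_pooled": null, "cal_range_high": 25},
    {"name": "SUL",        "kind": "parent",     "parent_of": null,  "istd": "FLO-d3",             "lod_synthetic": 0.0060, "loq_synthetic": 0.019, "lod_pooled": 0.030,  "loq_pooled": 0.10,  "blank_pooled": null, "cal_range_high": 25},
    {"name": "IMZ",        "kind": "parent",     "parent_of": null,  "istd": "IMZ-d4",             "lod_synthetic": 0.025,  "loq_synthetic": 0.050, "lod_pooled": 0.14,   "loq_pooled": 0.46,  "blank_pooled": null, "cal_range_high": 25},
    {"name": "ACE-N-DES",  "kind": "metabolite", "parent_of": "ACE", "istd": "ACE-N-DES-13C15N",   "lod_synthetic": 0.0090, "loq_synthetic": 0.030, "lod_pooled": 0.033,  "loq_pooled": 0.11,  "blank_pooled": 0.10, "cal_range_high": 25},
    {"name": "CLO-N-DES",  "kind": "metabolite", "parent_of": "CLO", "istd": "CLO-N-DES-13C15N2",  "lod_synthetic": 0.018,  "loq_synthetic": 0.060, "lod_pooled": 0.056,  "loq_pooled": 0.19,  "blank_pooled": 0.11, "cal_range_high": 25},
    {"name": "CLO-U",      "kind": "metabolite", "parent_of": "CLO", "istd": "CLO-d3",             "lod_synthetic": 0.011,  "loq_synthetic": 0.035, "lod_pooled": 0.053,  "loq_pooled": 0.18,  "blank_pooled": null, "cal_range_high": 10},
    {"name": "5-OH-IMI",   "kind": "metabolite", "parent_of": "IMI", "istd": "5-OH-IMI-13C15N2",   "lod_synthetic": 0.0070, "loq_synthetic": 0.023, "lod_pooled": 0.081,  "loq_pooled": 0.27,  "blank_pooled": 0.10, "cal_range_high": 25},
    {"name": "IMI-U",      "kind": "metabolite", "parent_of": "IMI", "istd": "IMI-d4",             "lod_synthetic": 0.0070, "loq_synthetic": 0.024, "lod_pooled": 0.0070, "loq_pooled": 0.024, "blank_pooled": null, "cal_range_high": 25},
    {"name": "IMI-O",      "kind": "metabolite", "parent_of": "IMI", "istd": "IMI-O-13C15N2",      "lod_synthetic": 0.013,  "loq_synthetic": 0.024, "lod_pooled": 0.052,  "loq_pooled": 0.18,  "blank_pooled": 0.10, "cal_range_high": 25},
    {"name": "THC-A",      "kind": "metabolite", "parent_of": "THC", "istd": "THC-A-13C6",         "lod_synthetic": 0.0070, "loq_synthetic": 0.023, "lod_pooled": 0.0090, "loq_pooled": 0.030, "blank_pooled": null, "cal_range_high": 25},
    {"name": "THX-N-DES",  "kind": "metabolite", "parent_of": "THX", "istd": "THX-d3",             "lod_synthetic": 0.0080, "loq_synthetic": 0.025, "lod_pooled": 0.031,  "loq_pooled": 0.10,  "blank_pooled": null, "cal_range_high": 25},
    {"name": "THX-U",      "kind": "metabolite", "parent_of": "THX", "istd": "THX-d3",             "lod_synthetic": 0.0050, "loq_synthetic": 0.017, "lod_pooled": 0.037,  "loq_pooled": 0.12,  "blank_pooled": 0.13, "cal_range_high": 25},
    {"name": "NIT-N-DES",  "kind": "metabolite", "parent_of": "NIT", "istd": "NIT-d3",             "lod_synthetic": 0.011,  "loq_synthetic": 0.035, "lod_pooled": 0.021,  "loq_pooled": 0.069, "blank_pooled": null, "cal_range_high": 25},
    {"name": "SUL-X",      "kind": "metabolite", "parent_of": "SUL", "istd": "FLO-d3",             "lod_synthetic": 0.010,  "loq_synthetic": 0.034, "lod_pooled": 0.026,  "loq_pooled": 0.087, "blank_pooled": null, "cal_range_high": 25}
  ],
  "aggregates": {
    "sum_ACE": ["ACE", "ACE-N-DES"],
    "sum_CLO": ["CLO", "CLO-U", "CLO-N-DES"],
    "sum_IMI": ["IMI", "5-OH-IMI", "IMI-O", "IMI-U"],
    "sum_THX": ["THX", "THX-N-DES", "THX-U", "CLO", "CLO-U", "CLO-N-DES"],
    "sum_NEO": ["ACE", "CLO", "IMI", "THC", "THX", "NIT", "FLU", "FLO", "SUL", "IMZ",
                "ACE-N-DES", "CLO-N-DES", "CLO-U", "5-OH-IMI", "IMI-U", "IMI-O",
                "THC-A", "THX-N-DES", "THX-U", "NIT-N-DES", "SUL-X"]
  }
}
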