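[
  {"sample_peak": 0,  "ref_id": null,     "note": "likely an artifact peak; no annotated structure"},
  {"sample_peak": 4,  "ref_id": null,     "note": "arises from the overlap of the adjacent peaks' tails; excluded"},
  {"sample_peak": 5,  "ref_id": 5,        "note": "overlap-resolved visually; single reference match kept"},
  {"sample_peak": 10, "ref_id": 12,       "note": "not prominent in the reference spectrum; matched visually"},
  {"sample_peak": 15, "ref_id": [19, 20], "note": "reference peaks form an unresolved plateau; both assigned"},
  {"sample_peak": 27, "ref_id": 42,       "note": "trailing peak of a four-peak series; matched visually"}
]
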