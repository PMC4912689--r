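{
  "description": "Color legend for fold-change heat categories written to PDB B-factors",
  "categories": [
    {"category": "no_effect", "code": 0, "color": "teal", "meaning": "assessed, no significant change (or < 3-fold)"},
    {"category": "fold_3_5", "code": 1, "color": "yellow", "meaning": "significant 3- to 5-fold loss"},
    {"category": "fold_5_10", "code": 2, "color": "pale orange", "meaning": "significant 5- to 10-fold loss"},
    {"category": "fold_10_30", "code": 3, "color": "orange", "meaning": "significant 10- to 30-fold loss"},
    {"category": "fold_gt_30", "code": 4, "color": "red", "meaning": "significant > 30-fold loss or no detectable response"},
    {"category": "enhanced", "code": 5, "color": "blue", "meaning": "significant gain of function"},
    {"category": "not_determined", "code": -1, "color": "grey", "meaning": "could not be assessed"},
    {"category": "unannotated", "code": -9, "color": "white", "meaning": "sentinel: residue outside the annotation set"}
  ]
}
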