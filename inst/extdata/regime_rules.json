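[
  {"taxonomy": "constant", "label": "i",
   "when": {"jbo": [null, 0.03], "jbb": [null, 0.03], "joo": [null, 0.03]},
   "note": "no heterotypic adhesion, both homotypic weak: all dispersed"},
  {"taxonomy": "constant", "label": "ii",
   "when": {"jbo": [null, 0.03], "joo": [null, 0.03]},
   "note": "blue clusters, orange dispersed"},
  {"taxonomy": "constant", "label": "iii",
   "when": {"jbo": [null, 0.03], "jbb": [null, 0.03]},
   "note": "orange clusters, blue dispersed"},
  {"taxonomy": "constant", "label": "iv",
   "when": {"jbo": [null, 0.03]},
   "note": "both homotypic strong, no heterotypic: separately sorted"},
  {"taxonomy": "constant", "label": "vi",
   "when": {"jbb": [null, 0.03], "joo": [null, 0.03]},
   "note": "heterotypic active, both homotypic weak: thin stripes"},
  {"taxonomy": "constant", "label": "viii",
   "when": {"jbb": [null, 0.03]},
   "note": "blue near zero, orange clusters: blue hexagonal spots in orange"},
  {"taxonomy": "constant", "label": "vii",
   "when": {"joo": [null, 0.03], "jbo": [null, 0.09]},
   "note": "orange weak at low heterotypic: orange spots in sparse blue"},
  {"taxonomy": "constant", "label": "vii",
   "when": {"joo": [null, 0.03], "jbb": [0.17, null]},
   "note": "strongest blue-blue: orange spots in sparser blue"},
  {"taxonomy": "constant", "label": "xi",
   "when": {"joo": [null, 0.03]},
   "note": "orange weak, moderate blue at higher heterotypic: packed blue"},
  {"taxonomy": "constant", "label": "xi",
   "when": {"jbo": [0.17, null], "jbb": [0.07, 0.11], "joo": [0.03, 0.07]},
   "note": "isolated hexagonal-spot pocket at strong heterotypic"},
  {"taxonomy": "constant", "label": "iv",
   "when": {"jbo": [0.03, 0.09], "abs_jbb_minus_jbo": [null, 0.02],
            "abs_joo_minus_jbo": [null, 0.02]},
   "note": "all three comparable and low: still sorts apart"},
  {"taxonomy": "constant", "label": "ix",
   "when": {"joo": [0.17, null], "jbb": [0.03, 0.13], "jbo": [null, 0.17]},
   "note": "strong orange, weak-intermediate blue: orange core, blue shell"},
  {"taxonomy": "constant", "label": "xii",
   "when": {"jbo": [0.09, null], "abs_joo_minus_jbo": [null, 0.045],
            "jbb": [0.03, null], "jbb_minus_joo": [null, 0]},
   "note": "orange-orange comparable to heterotypic, blue weaker: labyrinth"},
  {"taxonomy": "constant", "label": "v",
   "when": {"jbb_minus_jbo": [0, null], "joo_minus_jbo": [0, null]},
   "note": "both homotypic at least heterotypic: intermixed clusters"},
  {"taxonomy": "constant", "label": "vi",
   "when": {"abs_jbb_minus_joo": [null, 0.045], "jbb": [null, 0.09]},
   "note": "comparable weak homotypic below heterotypic: stripes"},
  {"taxonomy": "constant", "label": "x",
   "when": {"abs_jbb_minus_joo": [null, 0.045]},
   "note": "comparable intermediate homotypic: packed orange spots in blue"},
  {"taxonomy": "constant", "label": "x",
   "when": {"jbb_minus_joo": [0.045, null]},
   "note": "blue stronger than orange under heterotypic: orange spots"},
  {"taxonomy": "constant", "label": "vi",
   "when": {"jbb_minus_joo": [null, 0], "joo_minus_jbo": [null, 0]},
   "note": "orange stronger but below heterotypic: stripes"},
  {"taxonomy": "constant", "label": "v", "when": {},
   "note": "catch-all: intermixed"},

  {"taxonomy": "proliferation", "label": "v",
   "when": {"jbo": [null, 0.07], "abs_jbb_minus_joo": [null, 0.02]},
   "note": "weak heterotypic, comparable homotypic: intermixed"},
  {"taxonomy": "proliferation", "label": "xiv",
   "when": {"jbo": [null, 0.07], "jbb": [null, 0.07]},
   "note": "weak blue-blue: partially sorted, blue-rich"},
  {"taxonomy": "proliferation", "label": "xv",
   "when": {"jbo": [null, 0.07], "joo": [null, 0.07]},
   "note": "weak orange-orange: partially sorted, orange-rich"},
  {"taxonomy": "proliferation", "label": "v",
   "when": {"jbo": [null, 0.07]}, "note": "weak heterotypic catch-all"},
  {"taxonomy": "proliferation", "label": "v",
   "when": {"jbo": [null, 0.11], "abs_jbb_minus_joo": [null, 0.02],
            "jbb": [0.08, null]},
   "note": "comparable homotypic at/above heterotypic: intermixed"},
  {"taxonomy": "proliferation", "label": "vi",
   "when": {"jbo": [null, 0.11], "abs_jbb_minus_joo": [null, 0.02]},
   "note": "comparable weak homotypic: stripes"},
  {"taxonomy": "proliferation", "label": "vii",
   "when": {"jbo": [null, 0.11], "jbb": [0.17, null], "joo": [null, 0.13]},
   "note": "strong blue, weak orange: blue interior, orange periphery"},
  {"taxonomy": "proliferation", "label": "ix",
   "when": {"jbo": [null, 0.11], "joo": [0.17, null], "jbb": [null, 0.13]},
   "note": "strong orange, weak blue: orange interior, blue periphery"},
  {"taxonomy": "proliferation", "label": "xii",
   "when": {"jbo": [null, 0.11], "jbb": [0.11, 0.17], "joo": [null, 0.11]},
   "note": "slightly increased blue-blue: labyrinth"},
  {"taxonomy": "proliferation", "label": "xii",
   "when": {"jbo": [null, 0.11], "joo": [0.11, 0.17], "jbb": [null, 0.11]},
   "note": "slightly increased orange-orange: labyrinth"},
  {"taxonomy": "proliferation", "label": "vi",
   "when": {"jbo": [null, 0.11], "jbb": [null, 0.11], "joo": [null, 0.11]},
   "note": "both homotypic at or below heterotypic: stripes"},
  {"taxonomy": "proliferation", "label": "v",
   "when": {"jbo": [null, 0.11]}, "note": "band catch-all"},
  {"taxonomy": "proliferation", "label": "x",
   "when": {"jbo": [null, 0.19], "joo": [null, 0.11]},
   "note": "weak orange at intermediate heterotypic: packed orange spots"},
  {"taxonomy": "proliferation", "label": "vi",
   "when": {"jbo": [null, 0.19], "jbb": [null, 0.11],
            "abs_joo_minus_jbo": [null, 0.02]},
   "note": "weak blue, orange comparable to heterotypic: stripes"},
  {"taxonomy": "proliferation", "label": "ix",
   "when": {"jbo": [null, 0.19], "jbb": [0.07, 0.11], "joo": [0.21, null]},
   "note": "slightly increased blue under strong orange: core-shell"},
  {"taxonomy": "proliferation", "label": "xii",
   "when": {"jbo": [null, 0.19], "jbb": [null, 0.07], "joo": [0.19, null]},
   "note": "weak blue, strong orange: labyrinth"},
  {"taxonomy": "proliferation", "label": "v",
   "when": {"jbo": [null, 0.19]}, "note": "band catch-all"},
  {"taxonomy": "proliferation", "label": "v",
   "when": {"abs_jbb_minus_joo": [null, 0.02], "jbb": [0.21, null]},
   "note": "all three strong and comparable: intermixed"},
  {"taxonomy": "proliferation", "label": "vi",
   "when": {"abs_jbb_minus_joo": [null, 0.02]},
   "note": "comparable homotypic below strong heterotypic: stripes"},
  {"taxonomy": "proliferation", "label": "xi",
   "when": {"jbb": [0.07, 0.11], "joo": [0.03, 0.07]},
   "note": "hexagonal orange spots in tightly packed blue"},
  {"taxonomy": "proliferation", "label": "x",
   "when": {"jbb_minus_joo": [0.02, null]},
   "note": "blue stronger: circular orange spots in blue"},
  {"taxonomy": "proliferation", "label": "xiii",
   "when": {"jbb": [null, 0.07]},
   "note": "weak blue at strong heterotypic: mixed stripes and spots"},
  {"taxonomy": "proliferation", "label": "xii",
   "when": {"jbb_minus_joo": [null, 0]},
   "note": "orange stronger: labyrinth"},
  {"taxonomy": "proliferation", "label": "v", "when": {},
   "note": "catch-all: intermixed"}
]
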