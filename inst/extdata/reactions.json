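{
  "comment": "Carbon atom-mapped reaction library for central carbon metabolism. Slots number substrate (resp. product) carbons consecutively in the listed order; map[i] gives the product slot receiving substrate slot i. Carbon indices follow standard biochemical numbering (glucose C1-C6, pyruvate C1=carboxyl..C3=methyl, OAA C1-C4, citrate C1-C4 from OAA and C5-C6 from acetyl-CoA, alpha-ketoglutarate C1=carboxyl adjacent to carbonyl).",
  "metabolites": [
    {"name": "glucose",   "carbons": 6},
    {"name": "g6p",       "carbons": 6},
    {"name": "f6p",       "carbons": 6},
    {"name": "dhap",      "carbons": 3},
    {"name": "g3p",       "carbons": 3},
    {"name": "pyruvate",  "carbons": 3},
    {"name": "lactate",   "carbons": 3},
    {"name": "alanine",   "carbons": 3},
    {"name": "accoa",     "carbons": 2},
    {"name": "co2",       "carbons": 1},
    {"name": "oaa",       "carbons": 4},
    {"name": "citrate",   "carbons": 6},
    {"name": "akg",       "carbons": 5},
    {"name": "succinate", "carbons": 4, "symmetric": true},
    {"name": "fumarate",  "carbons": 4, "symmetric": true},
    {"name": "malate",    "carbons": 4},
    {"name": "aspartate", "carbons": 4},
    {"name": "glutamine", "carbons": 5},
    {"name": "glutamate", "carbons": 5},
    {"name": "6pg",       "carbons": 6},
    {"name": "ru5p",      "carbons": 5},
    {"name": "r5p",       "carbons": 5},
    {"name": "x5p",       "carbons": 5},
    {"name": "e4p",       "carbons": 4},
    {"name": "s7p",       "carbons": 7}
  ],
  "reactions": [
    {"id": "hk",       "name": "hexokinase",
     "substrates": [{"met": "glucose", "carbons": 6}],
     "products":   [{"met": "g6p", "carbons": 6}],
     "map": [1, 2, 3, 4, 5, 6]},
    {"id": "gpi",      "name": "glucose-6-phosphate isomerase",
     "substrates": [{"met": "g6p", "carbons": 6}],
     "products":   [{"met": "f6p", "carbons": 6}],
     "map": [1, 2, 3, 4, 5, 6]},
    {"id": "aldolase", "name": "PFK + aldolase (lumped): F6P cleaved into triose phosphates; C1-C3 -> DHAP (inverted), C4-C6 -> G3P",
     "substrates": [{"met": "f6p", "carbons": 6}],
     "products":   [{"met": "dhap", "carbons": 3}, {"met": "g3p", "carbons": 3}],
     "map": [3, 2, 1, 4, 5, 6]},
    {"id": "tpi",      "name": "triose-phosphate isomerase (DHAP C1<->C3 inversion)",
     "substrates": [{"met": "dhap", "carbons": 3}],
     "products":   [{"met": "g3p", "carbons": 3}],
     "map": [3, 2, 1]},
    {"id": "pyk",      "name": "lower glycolysis GAPDH..pyruvate kinase (lumped): G3P C1 -> pyruvate carboxyl",
     "substrates": [{"met": "g3p", "carbons": 3}],
     "products":   [{"met": "pyruvate", "carbons": 3}],
     "map": [1, 2, 3]},
    {"id": "ldh",      "name": "lactate dehydrogenase",
     "substrates": [{"met": "pyruvate", "carbons": 3}],
     "products":   [{"met": "lactate", "carbons": 3}],
     "map": [1, 2, 3]},
    {"id": "gpt1",     "name": "alanine transaminase",
     "substrates": [{"met": "pyruvate", "carbons": 3}],
     "products":   [{"met": "alanine", "carbons": 3}],
     "map": [1, 2, 3]},
    {"id": "pdh",      "name": "pyruvate dehydrogenase complex: C1 released as CO2",
     "substrates": [{"met": "pyruvate", "carbons": 3}],
     "products":   [{"met": "accoa", "carbons": 2}, {"met": "co2", "carbons": 1}],
     "map": [3, 1, 2]},
    {"id": "pc",       "name": "pyruvate carboxylase: CO2 added as OAA C4",
     "substrates": [{"met": "pyruvate", "carbons": 3}, {"met": "co2", "carbons": 1}],
     "products":   [{"met": "oaa", "carbons": 4}],
     "map": [1, 2, 3, 4]},
    {"id": "cs",       "name": "citrate synthase: OAA C1-C4 -> citrate C1-C4, acetyl C1-C2 -> citrate C5-C6",
     "substrates": [{"met": "accoa", "carbons": 2}, {"met": "oaa", "carbons": 4}],
     "products":   [{"met": "citrate", "carbons": 6}],
     "map": [5, 6, 1, 2, 3, 4]},
    {"id": "idh_ox",   "name": "aconitase + IDH (oxidative): OAA-derived citrate C1 released as CO2",
     "substrates": [{"met": "citrate", "carbons": 6}],
     "products":   [{"met": "akg", "carbons": 5}, {"met": "co2", "carbons": 1}],
     "map": [6, 1, 2, 3, 4, 5]},
    {"id": "akgdh",    "name": "alpha-KG dehydrogenase + succinyl-CoA synthetase (lumped): alpha-KG C1 released as CO2",
     "substrates": [{"met": "akg", "carbons": 5}],
     "products":   [{"met": "succinate", "carbons": 4}, {"met": "co2", "carbons": 1}],
     "map": [5, 1, 2, 3, 4]},
    {"id": "sdh",      "name": "succinate dehydrogenase",
     "substrates": [{"met": "succinate", "carbons": 4}],
     "products":   [{"met": "fumarate", "carbons": 4}],
     "map": [1, 2, 3, 4]},
    {"id": "fh",       "name": "fumarase",
     "substrates": [{"met": "fumarate", "carbons": 4}],
     "products":   [{"met": "malate", "carbons": 4}],
     "map": [1, 2, 3, 4]},
    {"id": "mdh",      "name": "malate dehydrogenase",
     "substrates": [{"met": "malate", "carbons": 4}],
     "products":   [{"met": "oaa", "carbons": 4}],
     "map": [1, 2, 3, 4]},
    {"id": "got2",     "name": "aspartate transaminase",
     "substrates": [{"met": "oaa", "carbons": 4}],
     "products":   [{"met": "aspartate", "carbons": 4}],
     "map": [1, 2, 3, 4]},
    {"id": "gls",      "name": "glutaminase",
     "substrates": [{"met": "glutamine", "carbons": 5}],
     "products":   [{"met": "glutamate", "carbons": 5}],
     "map": [1, 2, 3, 4, 5]},
    {"id": "gdh",      "name": "glutamate -> alpha-KG (GLUD1 / GPT2 / GOT2, carbon-equivalent)",
     "substrates": [{"met": "glutamate", "carbons": 5}],
     "products":   [{"met": "akg", "carbons": 5}],
     "map": [1, 2, 3, 4, 5]},
    {"id": "idh_red",  "name": "reverse IDH (reductive carboxylation): CO2 becomes citrate C1",
     "substrates": [{"met": "akg", "carbons": 5}, {"met": "co2", "carbons": 1}],
     "products":   [{"met": "citrate", "carbons": 6}],
     "map": [2, 3, 4, 5, 6, 1]},
    {"id": "acl",      "name": "ATP-citrate lyase: citrate C1-C4 -> OAA, C5-C6 -> acetyl-CoA",
     "substrates": [{"met": "citrate", "carbons": 6}],
     "products":   [{"met": "oaa", "carbons": 4}, {"met": "accoa", "carbons": 2}],
     "map": [1, 2, 3, 4, 5, 6]},
    {"id": "g6pdh",    "name": "glucose-6-phosphate dehydrogenase + lactonase (lumped)",
     "substrates": [{"met": "g6p", "carbons": 6}],
     "products":   [{"met": "6pg", "carbons": 6}],
     "map": [1, 2, 3, 4, 5, 6]},
    {"id": "pgd",      "name": "6-phosphogluconate dehydrogenase: glucose C1 released as CO2",
     "substrates": [{"met": "6pg", "carbons": 6}],
     "products":   [{"met": "ru5p", "carbons": 5}, {"met": "co2", "carbons": 1}],
     "map": [6, 1, 2, 3, 4, 5]},
    {"id": "rpi",      "name": "ribose-5-phosphate isomerase",
     "substrates": [{"met": "ru5p", "carbons": 5}],
     "products":   [{"met": "r5p", "carbons": 5}],
     "map": [1, 2, 3, 4, 5]},
    {"id": "rpe",      "name": "ribulose-5-phosphate epimerase (X5P -> Ru5P direction)",
     "substrates": [{"met": "x5p", "carbons": 5}],
     "products":   [{"met": "ru5p", "carbons": 5}],
     "map": [1, 2, 3, 4, 5]},
    {"id": "tkt1",     "name": "transketolase: 2-carbon unit from F6P C1-C2 onto G3P -> X5P + E4P",
     "substrates": [{"met": "f6p", "carbons": 6}, {"met": "g3p", "carbons": 3}],
     "products":   [{"met": "x5p", "carbons": 5}, {"met": "e4p", "carbons": 4}],
     "map": [1, 2, 6, 7, 8, 9, 3, 4, 5]},
    {"id": "tal",      "name": "transaldolase: 3-carbon unit from S7P C1-C3 onto G3P -> E4P + F6P",
     "substrates": [{"met": "s7p", "carbons": 7}, {"met": "g3p", "carbons": 3}],
     "products":   [{"met": "e4p", "carbons": 4}, {"met": "f6p", "carbons": 6}],
     "map": [5, 6, 7, 1, 2, 3, 4, 8, 9, 10]},
    {"id": "tkt2",     "name": "transketolase: 2-carbon unit from S7P C1-C2 onto G3P -> X5P; S7P C3-C7 -> R5P",
     "substrates": [{"met": "s7p", "carbons": 7}, {"met": "g3p", "carbons": 3}],
     "products":   [{"met": "r5p", "carbons": 5}, {"met": "x5p", "carbons": 5}],
     "map": [6, 7, 1, 2, 3, 4, 5, 8, 9, 10]}
  ]
}
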