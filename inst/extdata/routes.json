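{
  "comment": "Canonical single-pass label-propagation routes. Each step names a reaction from reactions.json; 'follow' selects which product carries the label forward (required when a reaction has two products); 'pools' declares where co-substrates come from: the string 'unlabeled' (all-12C, the default) or {\"route\": <name>} to condense with another route's terminal label distribution. These pool declarations are the explicit assumptions behind each predicted m+k value.",
  "tracers": {
    "U-13C6-glucose":   {"met": "glucose",   "labeled": [1, 2, 3, 4, 5, 6]},
    "U-13C5-glutamine": {"met": "glutamine", "labeled": [1, 2, 3, 4, 5]},
    "13C3-G3P":         {"met": "g3p",       "labeled": [1, 2, 3]}
  },
  "routes": [
    {"name": "glycolysis_pyruvate", "tracer": "U-13C6-glucose",
     "label": "glycolysis to pyruvate",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"}]},
    {"name": "glycolysis_lactate", "tracer": "U-13C6-glucose",
     "label": "glycolysis to lactate (LDH)",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "ldh"}]},
    {"name": "glycolysis_alanine", "tracer": "U-13C6-glucose",
     "label": "glycolysis to alanine (ALT/GPT1)",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "gpt1"}]},
    {"name": "pdh_accoa", "tracer": "U-13C6-glucose",
     "label": "PDH decarboxylation of glucose-derived pyruvate",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pdh", "follow": "accoa"}]},
    {"name": "pdh_citrate", "tracer": "U-13C6-glucose",
     "label": "PDH-derived acetyl-CoA condensed with unlabeled OAA",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pdh", "follow": "accoa"},
               {"reaction": "cs", "pools": {"oaa": "unlabeled"}}]},
    {"name": "pc_oaa", "tracer": "U-13C6-glucose",
     "label": "pyruvate carboxylase with unlabeled CO2",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pc", "pools": {"co2": "unlabeled"}}]},
    {"name": "pdh_pc_citrate", "tracer": "U-13C6-glucose",
     "label": "citrate from PC-derived OAA condensed with PDH-derived acetyl-CoA",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pc", "pools": {"co2": "unlabeled"}},
               {"reaction": "cs", "pools": {"accoa": {"route": "pdh_accoa"}}}]},
    {"name": "glucose_ox_tca_succinate", "tracer": "U-13C6-glucose",
     "label": "first-turn oxidative TCA from PDH-derived citrate to succinate",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pdh", "follow": "accoa"},
               {"reaction": "cs", "pools": {"oaa": "unlabeled"}},
               {"reaction": "idh_ox", "follow": "akg"},
               {"reaction": "akgdh", "follow": "succinate"}]},
    {"name": "glucose_ox_tca_malate", "tracer": "U-13C6-glucose",
     "label": "first-turn oxidative TCA from PDH-derived citrate to malate",
     "steps": [{"reaction": "hk"}, {"reaction": "gpi"},
               {"reaction": "aldolase", "follow": "g3p"}, {"reaction": "pyk"},
               {"reaction": "pdh", "follow": "accoa"},
               {"reaction": "cs", "pools": {"oaa": "unlabeled"}},
               {"reaction": "idh_ox", "follow": "akg"},
               {"reaction": "akgdh", "follow": "succinate"},
               {"reaction": "sdh"}, {"reaction": "fh"}]},
    {"name": "oxppp_6pg", "tracer": "U-13C6-glucose",
     "label": "oxidative PPP entry: G6PDH to 6-phosphogluconate",
     "steps": [{"reaction": "hk"}, {"reaction": "g6pdh"}]},
    {"name": "oxppp_r5p", "tracer": "U-13C6-glucose",
     "label": "oxidative PPP arm: 6PGD decarboxylation to ribose 5-phosphate",
     "steps": [{"reaction": "hk"}, {"reaction": "g6pdh"},
               {"reaction": "pgd", "follow": "ru5p"}, {"reaction": "rpi"}]},
    {"name": "nonoxppp_r5p", "tracer": "13C3-G3P",
     "label": "non-oxidative PPP arm: labeled G3P + unlabeled F6P to ribose 5-phosphate",
     "steps": [{"reaction": "tkt1", "follow": "x5p", "pools": {"f6p": "unlabeled"}},
               {"reaction": "rpe"}, {"reaction": "rpi"}]},
    {"name": "gls_glutamate", "tracer": "U-13C5-glutamine",
     "label": "glutaminase: glutamine to glutamate",
     "steps": [{"reaction": "gls"}]},
    {"name": "gln_akg", "tracer": "U-13C5-glutamine",
     "label": "glutamine to alpha-ketoglutarate (GLS then GLUD1/GPT2/GOT2)",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"}]},
    {"name": "gln_ox_succinate", "tracer": "U-13C5-glutamine",
     "label": "oxidative glutaminolysis to succinate",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "akgdh", "follow": "succinate"}]},
    {"name": "gln_ox_fumarate", "tracer": "U-13C5-glutamine",
     "label": "oxidative glutaminolysis to fumarate",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "akgdh", "follow": "succinate"}, {"reaction": "sdh"}]},
    {"name": "gln_ox_malate", "tracer": "U-13C5-glutamine",
     "label": "oxidative glutaminolysis to malate",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "akgdh", "follow": "succinate"}, {"reaction": "sdh"},
               {"reaction": "fh"}]},
    {"name": "gln_ox_aspartate", "tracer": "U-13C5-glutamine",
     "label": "oxidative glutaminolysis to aspartate via GOT2",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "akgdh", "follow": "succinate"}, {"reaction": "sdh"},
               {"reaction": "fh"}, {"reaction": "mdh"}, {"reaction": "got2"}]},
    {"name": "gln_ox_citrate", "tracer": "U-13C5-glutamine",
     "label": "oxidative glutaminolysis to citrate (condensation with unlabeled acetyl-CoA)",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "akgdh", "follow": "succinate"}, {"reaction": "sdh"},
               {"reaction": "fh"}, {"reaction": "mdh"},
               {"reaction": "cs", "pools": {"accoa": "unlabeled"}}]},
    {"name": "gln_red_citrate", "tracer": "U-13C5-glutamine",
     "label": "reductive carboxylation of alpha-KG to citrate (unlabeled CO2)",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "idh_red", "pools": {"co2": "unlabeled"}}]},
    {"name": "gln_red_aspartate", "tracer": "U-13C5-glutamine",
     "label": "reductive route: ATP-citrate lyase cleavage then GOT2 to aspartate",
     "steps": [{"reaction": "gls"}, {"reaction": "gdh"},
               {"reaction": "idh_red", "pools": {"co2": "unlabeled"}},
               {"reaction": "acl", "follow": "oaa"}, {"reaction": "got2"}]}
  ]
}
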