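{
  "id": "toy_branched",
  "metabolites": [
    {"id": "A_c", "compartment": "c"},
    {"id": "B_c", "compartment": "c"},
    {"id": "C_c", "compartment": "c"},
    {"id": "D_c", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "EX_A",
      "metabolites": {"A_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "subsystem": "exchange",
      "gene_reaction_rule": ""
    },
    {
      "id": "R_AB1",
      "metabolites": {"A_c": -1, "B_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "subsystem": "upper pathway",
      "gene_reaction_rule": "g1 and g2"
    },
    {
      "id": "R_AB2",
      "metabolites": {"A_c": -1, "B_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "subsystem": "upper pathway",
      "gene_reaction_rule": "g3"
    },
    {
      "id": "R_BC",
      "metabolites": {"B_c": -1, "C_c": 1},
      "lower_bound": -1000, "upper_bound": 1000,
      "subsystem": "lower pathway",
      "gene_reaction_rule": "g4 or g5"
    },
    {
      "id": "R_CD",
      "metabolites": {"C_c": -1, "D_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "subsystem": "lower pathway",
      "gene_reaction_rule": "g6"
    },
    {
      "id": "EX_D",
      "metabolites": {"D_c": -1},
      "lower_bound": 0, "upper_bound": 1000,
      "subsystem": "exchange",
      "gene_reaction_rule": ""
    }
  ],
  "genes": [
    {"id": "g1"}, {"id": "g2"}, {"id": "g3"},
    {"id": "g4"}, {"id": "g5"}, {"id": "g6"}
  ]
}
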