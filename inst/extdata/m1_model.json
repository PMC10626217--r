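{
  "id": "M1",
  "metabolites": [
    {
      "id": "glc",
      "compartment": "c"
    },
    {
      "id": "but",
      "compartment": "c"
    },
    {
      "id": "glc",
      "compartment": "e"
    },
    {
      "id": "but",
      "compartment": "e"
    }
  ],
  "reactions": [
    {
      "id": "t_glc",
      "stoichiometry": {
        "glc[e]": -1,
        "glc[c]": 1
      },
      "lower": 0,
      "upper": 1000
    },
    {
      "id": "r_but",
      "stoichiometry": {
        "glc[c]": -1,
        "but[c]": 1
      },
      "lower": 0,
      "upper": 1000
    },
    {
      "id": "t_but",
      "stoichiometry": {
        "but[c]": -1,
        "but[e]": 1
      },
      "lower": 0,
      "upper": 1000
    },
    {
      "id": "bm",
      "stoichiometry": {
        "glc[c]": -1
      },
      "lower": 0,
      "upper": 1000
    },
    {
      "id": "EX_glc",
      "stoichiometry": {
        "glc[e]": -1
      },
      "lower": -1000,
      "upper": 1000
    },
    {
      "id": "EX_but",
      "stoichiometry": {
        "but[e]": -1
      },
      "lower": -1000,
      "upper": 1000
    }
  ],
  "biomass_reaction": "bm",
  "exchange_reactions": [
    "EX_glc",
    "EX_but"
  ]
}
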