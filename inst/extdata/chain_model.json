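{
  "metabolites": [
    {
      "id": "A_c",
      "name": "A_c",
      "compartment": "c"
    },
    {
      "id": "B_c",
      "name": "B_c",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "name": "EX_A",
      "stoichiometry": {
        "A_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "pathway": "uptake",
      "compartment": "c",
      "genes": [],
      "exchange": true
    },
    {
      "id": "R_AB",
      "name": "R_AB",
      "stoichiometry": {
        "A_c": -1,
        "B_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "core",
      "compartment": "c",
      "genes": [
        "G1",
        "G2"
      ],
      "exchange": false
    },
    {
      "id": "BIO",
      "name": "BIO",
      "stoichiometry": {
        "B_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "biomass",
      "compartment": "c",
      "genes": [],
      "exchange": true
    }
  ],
  "objective": "BIO"
}
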