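{
  "metabolites": [
    {
      "id": "Glc_c",
      "name": "Glc_c",
      "compartment": "c"
    },
    {
      "id": "G6P_c",
      "name": "G6P_c",
      "compartment": "c"
    },
    {
      "id": "PYR_c",
      "name": "PYR_c",
      "compartment": "c"
    },
    {
      "id": "FA_c",
      "name": "FA_c",
      "compartment": "c"
    },
    {
      "id": "TAG_c",
      "name": "TAG_c",
      "compartment": "c"
    },
    {
      "id": "AA_c",
      "name": "AA_c",
      "compartment": "c"
    },
    {
      "id": "Protein_c",
      "name": "Protein_c",
      "compartment": "c"
    },
    {
      "id": "ATP_c",
      "name": "ATP_c",
      "compartment": "c"
    },
    {
      "id": "CO2_c",
      "name": "CO2_c",
      "compartment": "c"
    },
    {
      "id": "G6P_p",
      "name": "G6P_p",
      "compartment": "p"
    },
    {
      "id": "PYR_p",
      "name": "PYR_p",
      "compartment": "p"
    },
    {
      "id": "AcCoA_p",
      "name": "AcCoA_p",
      "compartment": "p"
    },
    {
      "id": "FA_p",
      "name": "FA_p",
      "compartment": "p"
    },
    {
      "id": "ADPG_p",
      "name": "ADPG_p",
      "compartment": "p"
    },
    {
      "id": "Starch_p",
      "name": "Starch_p",
      "compartment": "p"
    },
    {
      "id": "PYR_m",
      "name": "PYR_m",
      "compartment": "m"
    },
    {
      "id": "CO2_m",
      "name": "CO2_m",
      "compartment": "m"
    },
    {
      "id": "ATP_m",
      "name": "ATP_m",
      "compartment": "m"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "name": "EX_glc",
      "stoichiometry": {
        "Glc_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "pathway": "sugar_uptake",
      "compartment": "c",
      "genes": [],
      "exchange": true
    },
    {
      "id": "HXK_c",
      "name": "HXK_c",
      "stoichiometry": {
        "Glc_c": -1,
        "G6P_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "glycolysis",
      "compartment": "c",
      "genes": [],
      "exchange": false
    },
    {
      "id": "GLYC_c",
      "name": "GLYC_c",
      "stoichiometry": {
        "G6P_c": -1,
        "PYR_c": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "glycolysis",
      "compartment": "c",
      "genes": [],
      "exchange": false
    },
    {
      "id": "GPT_cp",
      "name": "GPT_cp",
      "stoichiometry": {
        "G6P_c": -1,
        "G6P_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "cp",
      "genes": [],
      "exchange": false
    },
    {
      "id": "GLYC_p",
      "name": "GLYC_p",
      "stoichiometry": {
        "G6P_p": -1,
        "PYR_p": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "glycolysis",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "OPP_p",
      "name": "OPP_p",
      "stoichiometry": {
        "G6P_p": -1,
        "PYR_p": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "pentose_phosphate",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "PYR_cp",
      "name": "PYR_cp",
      "stoichiometry": {
        "PYR_c": -1,
        "PYR_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "cp",
      "genes": [],
      "exchange": false
    },
    {
      "id": "PYR_cm",
      "name": "PYR_cm",
      "stoichiometry": {
        "PYR_c": -1,
        "PYR_m": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "cm",
      "genes": [],
      "exchange": false
    },
    {
      "id": "PDH_p",
      "name": "PDH_p",
      "stoichiometry": {
        "PYR_p": -1,
        "AcCoA_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "fatty_acid_synthesis",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "FAS_p",
      "name": "FAS_p",
      "stoichiometry": {
        "AcCoA_p": -3,
        "FA_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "fatty_acid_synthesis",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "FAX_pc",
      "name": "FAX_pc",
      "stoichiometry": {
        "FA_p": -1,
        "FA_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "pc",
      "genes": [],
      "exchange": false
    },
    {
      "id": "TAGS_c",
      "name": "TAGS_c",
      "stoichiometry": {
        "FA_c": -1,
        "TAG_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "tag_synthesis",
      "compartment": "c",
      "genes": [],
      "exchange": false
    },
    {
      "id": "AGP_p",
      "name": "AGP_p",
      "stoichiometry": {
        "G6P_p": -1,
        "ADPG_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "starch_synthesis",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "SS_p",
      "name": "SS_p",
      "stoichiometry": {
        "ADPG_p": -1,
        "Starch_p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "starch_synthesis",
      "compartment": "p",
      "genes": [],
      "exchange": false
    },
    {
      "id": "AAS_c",
      "name": "AAS_c",
      "stoichiometry": {
        "PYR_c": -1,
        "AA_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "protein_synthesis",
      "compartment": "c",
      "genes": [],
      "exchange": false
    },
    {
      "id": "PROT_c",
      "name": "PROT_c",
      "stoichiometry": {
        "AA_c": -2,
        "Protein_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "protein_synthesis",
      "compartment": "c",
      "genes": [],
      "exchange": false
    },
    {
      "id": "TCA_m",
      "name": "TCA_m",
      "stoichiometry": {
        "PYR_m": -1,
        "CO2_m": 3,
        "ATP_m": 5
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "tca",
      "compartment": "m",
      "genes": [],
      "exchange": false
    },
    {
      "id": "ATP_mc",
      "name": "ATP_mc",
      "stoichiometry": {
        "ATP_m": -1,
        "ATP_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "mc",
      "genes": [],
      "exchange": false
    },
    {
      "id": "CO2_mc",
      "name": "CO2_mc",
      "stoichiometry": {
        "CO2_m": -1,
        "CO2_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "transport",
      "compartment": "mc",
      "genes": [],
      "exchange": false
    },
    {
      "id": "EX_co2",
      "name": "EX_co2",
      "stoichiometry": {
        "CO2_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "exchange",
      "compartment": "c",
      "genes": [],
      "exchange": true
    },
    {
      "id": "BIOMASS",
      "name": "BIOMASS",
      "stoichiometry": {
        "TAG_c": -0.333333333333333,
        "Starch_p": -0.333333333333333,
        "Protein_c": -0.333333333333333,
        "ATP_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "pathway": "biomass",
      "compartment": "c",
      "genes": [],
      "exchange": false
    }
  ],
  "objective": "BIOMASS"
}
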