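{
  "nodes": [
    {
      "id": "glucose",
      "group": "glycolysis"
    },
    {
      "id": "pyruvate",
      "group": "glycolysis"
    },
    {
      "id": "lactate",
      "group": "glycolysis"
    },
    {
      "id": "citrate",
      "group": "glycolysis"
    },
    {
      "id": "isoleucine",
      "group": "bcaa"
    },
    {
      "id": "leucine",
      "group": "bcaa"
    },
    {
      "id": "valine",
      "group": "bcaa"
    },
    {
      "id": "alanine",
      "group": "other_aa"
    },
    {
      "id": "phenylalanine",
      "group": "other_aa"
    },
    {
      "id": "tyrosine",
      "group": "other_aa"
    },
    {
      "id": "glutamine",
      "group": "other_aa"
    },
    {
      "id": "histidine",
      "group": "other_aa"
    },
    {
      "id": "glycine",
      "group": "other_aa"
    },
    {
      "id": "acetoacetate",
      "group": "ketone"
    },
    {
      "id": "acetone",
      "group": "ketone"
    },
    {
      "id": "hydroxybutyrate",
      "group": "ketone"
    }
  ],
  "edges": [
    {
      "substrate": "glucose",
      "product": "pyruvate",
      "enzymes": [
        "ENZ_GLC_PYR"
      ],
      "reversible": true
    },
    {
      "substrate": "pyruvate",
      "product": "lactate",
      "enzymes": [
        "ENZ_PYR_LAC"
      ],
      "reversible": true
    },
    {
      "substrate": "lactate",
      "product": "glucose",
      "enzymes": [
        "ENZ_LAC_GLC"
      ],
      "reversible": false
    },
    {
      "substrate": "pyruvate",
      "product": "citrate",
      "enzymes": [
        "ENZ_PYR_CIT"
      ],
      "reversible": false
    },
    {
      "substrate": "alanine",
      "product": "pyruvate",
      "enzymes": [
        "ENZ_ALA_PYR"
      ],
      "reversible": true
    },
    {
      "substrate": "glycine",
      "product": "pyruvate",
      "enzymes": [
        "ENZ_GLY_PYR"
      ],
      "reversible": true
    },
    {
      "substrate": "glutamine",
      "product": "citrate",
      "enzymes": [
        "ENZ_GLN_CIT"
      ],
      "reversible": false
    },
    {
      "substrate": "histidine",
      "product": "glutamine",
      "enzymes": [
        "ENZ_HIS_GLN"
      ],
      "reversible": false
    },
    {
      "substrate": "phenylalanine",
      "product": "tyrosine",
      "enzymes": [
        "ENZ_PHE_TYR"
      ],
      "reversible": false
    },
    {
      "substrate": "tyrosine",
      "product": "acetoacetate",
      "enzymes": [
        "ENZ_TYR_ACA"
      ],
      "reversible": false
    },
    {
      "substrate": "pyruvate",
      "product": "acetoacetate",
      "enzymes": [
        "ENZ_PYR_ACA"
      ],
      "reversible": false
    },
    {
      "substrate": "isoleucine",
      "product": "citrate",
      "enzymes": [
        "ENZ_ILE_CIT"
      ],
      "reversible": false
    },
    {
      "substrate": "valine",
      "product": "citrate",
      "enzymes": [
        "ENZ_VAL_CIT"
      ],
      "reversible": false
    },
    {
      "substrate": "leucine",
      "product": "acetoacetate",
      "enzymes": [
        "ENZ_LEU_ACA"
      ],
      "reversible": false
    },
    {
      "substrate": "acetoacetate",
      "product": "acetone",
      "enzymes": [
        "ENZ_ACA_ACE"
      ],
      "reversible": false
    },
    {
      "substrate": "acetoacetate",
      "product": "hydroxybutyrate",
      "enzymes": [
        "ENZ_ACA_BHB"
      ],
      "reversible": true
    }
  ],
  "transporters": {
    "TRANS_ALA": "alanine",
    "TRANS_BCAA": ["isoleucine", "leucine", "valine"],
    "TRANS_GLN": "glutamine",
    "TRANS_GLC": "glucose",
    "TRANS_KET": ["acetoacetate", "hydroxybutyrate"]
  },
  "regulators": [
    {
      "gene_id": "TF_LIPO",
      "entry_node": "glucose",
      "sign": 1
    },
    {
      "gene_id": "TF_AMINO",
      "entry_node": "phenylalanine",
      "sign": 1
    },
    {
      "gene_id": "TF_KETO",
      "entry_node": "leucine",
      "sign": 1
    },
    {
      "gene_id": "TF_CATAB",
      "entry_node": "histidine",
      "sign": 1
    },
    {
      "gene_id": "TF_BCAA",
      "entry_node": "valine",
      "sign": 1
    },
    {
      "gene_id": "TF_GLY",
      "entry_node": "glycine",
      "sign": 1
    }
  ]
}
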