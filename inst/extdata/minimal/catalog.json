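{
  "pathways": [
    {
      "gene_id": "GH1",
      "level1": "Metabolism",
      "level2": "Metabolism (level 2)",
      "level3": "Energy metabolism"
    },
    {
      "gene_id": "K00001",
      "level1": "Metabolism",
      "level2": "Metabolism (level 2)",
      "level3": "Glycolysis / Gluconeogenesis"
    },
    {
      "gene_id": "K00002",
      "level1": "Metabolism",
      "level2": "Metabolism (level 2)",
      "level3": "Glycolysis / Gluconeogenesis"
    },
    {
      "gene_id": "K90001",
      "level1": "Metabolism",
      "level2": "Metabolism (level 2)",
      "level3": "Energy metabolism"
    }
  ],
  "mechanisms": [
    {
      "mechanism_id": "cfix1",
      "category": "c_fixation",
      "genes": "K80001"
    },
    {
      "mechanism_id": "cfix2",
      "category": "c_fixation",
      "genes": "K80002"
    },
    {
      "mechanism_id": "cfix3",
      "category": "c_fixation",
      "genes": "K80003"
    },
    {
      "mechanism_id": "cfix4",
      "category": "c_fixation",
      "genes": "K80004"
    },
    {
      "mechanism_id": "cfix5",
      "category": "c_fixation",
      "genes": "K80005"
    },
    {
      "mechanism_id": "cfix6",
      "category": "c_fixation",
      "genes": "K80006"
    },
    {
      "mechanism_id": "cfix7",
      "category": "c_fixation",
      "genes": "K80007"
    },
    {
      "mechanism_id": "AA",
      "category": "cazyme",
      "genes": "AA1"
    },
    {
      "mechanism_id": "CBM",
      "category": "cazyme",
      "genes": "CBM1"
    },
    {
      "mechanism_id": "CE",
      "category": "cazyme",
      "genes": "CE1"
    },
    {
      "mechanism_id": "GH",
      "category": "cazyme",
      "genes": "GH1"
    },
    {
      "mechanism_id": "GT",
      "category": "cazyme",
      "genes": "GT1"
    },
    {
      "mechanism_id": "PL",
      "category": "cazyme",
      "genes": "PL1"
    },
    {
      "mechanism_id": "K_uptake",
      "category": "salt_resistance",
      "genes": "K90002"
    },
    {
      "mechanism_id": "Na_extrusion",
      "category": "salt_resistance",
      "genes": "K90001"
    },
    {
      "mechanism_id": "osmotic_solute",
      "category": "salt_resistance",
      "genes": "K90003"
    }
  ]
}
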