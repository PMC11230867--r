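{
  "note": "Miniature synthetic pathway library for serum NMR metabolites. Schema-compatible stand-in for a KEGG-derived compound/pathway graph library; memberships and edges are plausible but reduced, not an export of any database.",
  "pathways": [
    {
      "name": "Valine, leucine and isoleucine degradation",
      "compounds": ["valine", "leucine", "isoleucine", "isovalerate",
                    "2-oxocaproate", "3-methyl-2-oxovalerate"],
      "edges": [["leucine", "isovalerate"],
                ["isovalerate", "2-oxocaproate"],
                ["isoleucine", "3-methyl-2-oxovalerate"],
                ["valine", "3-methyl-2-oxovalerate"],
                ["2-oxocaproate", "3-methyl-2-oxovalerate"]]
    },
    {
      "name": "Citrate cycle (TCA cycle)",
      "compounds": ["citrate", "succinate", "fumarate", "malate", "oxaloacetate"],
      "edges": [["citrate", "succinate"], ["succinate", "fumarate"],
                ["fumarate", "malate"], ["malate", "oxaloacetate"],
                ["oxaloacetate", "citrate"]]
    },
    {
      "name": "Glycolysis / Gluconeogenesis",
      "compounds": ["glucose", "pyruvate", "lactate", "acetate"],
      "edges": [["glucose", "pyruvate"], ["pyruvate", "lactate"],
                ["pyruvate", "acetate"]]
    },
    {
      "name": "Glycine, serine and threonine metabolism",
      "compounds": ["glycine", "serine", "n,n-dimethylglycine", "sarcosine",
                    "creatine"],
      "edges": [["n,n-dimethylglycine", "sarcosine"],
                ["sarcosine", "glycine"], ["glycine", "serine"],
                ["glycine", "creatine"]]
    },
    {
      "name": "Pentose and glucuronate interconversions",
      "compounds": ["glucose", "gluconate", "glucuronate"],
      "edges": [["glucose", "gluconate"], ["glucose", "glucuronate"]]
    },
    {
      "name": "Pyrimidine metabolism",
      "compounds": ["ump", "uridine", "uracil"],
      "edges": [["ump", "uridine"], ["uridine", "uracil"]]
    },
    {
      "name": "Tryptophan metabolism",
      "compounds": ["tryptophan", "kynurenine", "kynurenate"],
      "edges": [["tryptophan", "kynurenine"], ["kynurenine", "kynurenate"]]
    },
    {
      "name": "Arginine and proline metabolism",
      "compounds": ["glutamate", "proline", "ornithine", "arginine"],
      "edges": [["glutamate", "proline"], ["glutamate", "ornithine"],
                ["ornithine", "arginine"]]
    },
    {
      "name": "Inositol phosphate metabolism",
      "compounds": ["myo-inositol", "inositol-1-phosphate"],
      "edges": [["myo-inositol", "inositol-1-phosphate"]]
    },
    {
      "name": "Taurine and hypotaurine metabolism",
      "compounds": ["taurine", "hypotaurine"],
      "edges": [["taurine", "hypotaurine"]]
    },
    {
      "name": "Alanine, aspartate and glutamate metabolism",
      "compounds": ["alanine", "aspartate", "glutamate", "succinate",
                    "fumarate"],
      "edges": [["alanine", "glutamate"], ["glutamate", "aspartate"],
                ["aspartate", "fumarate"], ["succinate", "fumarate"]]
    },
    {
      "name": "Lysine degradation",
      "compounds": ["lysine", "n6-acetyllysine", "glutarate"],
      "edges": [["lysine", "n6-acetyllysine"], ["lysine", "glutarate"]]
    },
    {
      "name": "Glycerolipid metabolism",
      "compounds": ["glycerol", "glycerol 3-phosphate"],
      "edges": [["glycerol", "glycerol 3-phosphate"]]
    }
  ]
}
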