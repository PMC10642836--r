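{
  "description": "Curated node-to-gene mapping for the MAPK, PI3K-AKT and cell-cycle overlay figures. Best-effort curation from standard HGNC symbols; user-overridable.",
  "pathways": {
    "MAPK": {
      "nodes": {
        "NGF": ["NGF"],
        "NT3/4": ["NTF3", "NTF4"],
        "EGF": ["EGF"],
        "PDGF": ["PDGFA", "PDGFB"],
        "PDGFR": ["PDGFRA", "PDGFRB"],
        "IGF-1R": ["IGF1R"],
        "SOS": ["SOS1", "SOS2"],
        "RAS": ["HRAS", "KRAS", "NRAS"],
        "MEK": ["MAP2K1", "MAP2K2"],
        "MEKK1": ["MAP3K1"],
        "JNK": ["MAPK8", "MAPK9"],
        "c-JUN": ["JUN"],
        "Myc": ["MYC"],
        "P53": ["TP53"],
        "FASL": ["FASLG"],
        "TNF": ["TNF"],
        "CASP": ["CASP3", "CASP8"],
        "DAXX": ["DAXX"]
      }
    },
    "PI3K-AKT": {
      "nodes": {
        "GF": ["IGF1", "FGF2"],
        "ECM": ["FN1", "COL4A1"],
        "ITG-A/B": ["ITGA2", "ITGB1"],
        "PI3K": ["PIK3CA", "PIK3CB", "PIK3R1"],
        "PTEN": ["PTEN"],
        "AKT": ["AKT1", "AKT2"],
        "GSK-3b": ["GSK3B"],
        "p21": ["CDKN1A"],
        "Bcl-2": ["BCL2"],
        "Bcl-xL": ["BCL2L1"],
        "MEK": ["MAP2K1", "MAP2K2"],
        "Myc": ["MYC"],
        "TGF-b": ["TGFB1", "TGFB2"],
        "SMAD2/3": ["SMAD2", "SMAD3"]
      }
    },
    "cell-cycle": {
      "nodes": {
        "TGF-b": ["TGFB1", "TGFB2"],
        "SMAD2/3": ["SMAD2", "SMAD3"],
        "P15": ["CDKN2B"],
        "P19": ["CDKN2D"],
        "p21": ["CDKN1A"],
        "CycD": ["CCND1", "CCND2", "CCND3"],
        "CDK4/6": ["CDK4", "CDK6"],
        "E2F1/2/3": ["E2F1", "E2F2", "E2F3"],
        "P300": ["EP300"],
        "P53": ["TP53"],
        "Bcl-2": ["BCL2"],
        "Bcl-xL": ["BCL2L1"]
      }
    }
  }
}
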