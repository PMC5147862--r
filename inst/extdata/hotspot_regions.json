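{
  "comment": "Published spans of the dense interaction regions, used only for labeling/comparison of detected regions, never as detection input. R4 and R5 are shown only graphically in the source figure and carry no printed spans; they are therefore omitted here.",
  "numbering": {"rows": "HRAS", "cols": "CRAF"},
  "regions": {
    "R1": {"rows": [37, 38, 39], "cols": [66, 67, 68, 69],
           "note": "intermolecular anti-parallel beta-sheet recognition stretch; largely main-chain/main-chain"},
    "R2": {"rows_range": [21, 34], "cols_range": [83, 90],
           "note": "N-terminal half of switch I vs effector helical segment"},
    "R3": {"rows": [36, 37, 64], "cols": [57, 59, 71],
           "note": "proposed RAS-vs-RRAS isoform selectivity region"}
  }
}
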