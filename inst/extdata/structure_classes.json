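{
  "comment": "Ordered decision tables for exon-intron structure classes (hop h1-h6, chl-fus f1-f5) and combined gene-arrangement letters (A-J). intron_count is a scalar or an inclusive [min,max] range; phase_signature, when present, must match exactly. First matching rule wins.",
  "hop": [
    { "label": "h1", "intron_count": 0,
      "notes": "intronless green-algal form" },
    { "label": "h2", "intron_count": 1, "phase_signature": [0],
      "notes": "single 5' phase-0 intron after the miniexon" },
    { "label": "h3", "intron_count": 12,
      "notes": "intron-rich chlorophyte form, mostly phase-0" },
    { "label": "h4", "intron_count": [7, 8],
      "notes": "non-angiosperm land-plant form" },
    { "label": "h5", "intron_count": 6,
      "notes": "dominant angiosperm form; I_h phase-0 splits TPR2A" },
    { "label": "h6", "intron_count": 5,
      "notes": "h5 minus the phase-0 intron V_h inside DP2" }
  ],
  "fus": [
    { "label": "f1", "intron_count": 1, "phase_signature": [1],
      "notes": "single phase-1 transit-peptide intron" },
    { "label": "f2", "intron_count": 9,
      "notes": "transit-peptide intron plus eight phase-0 introns" },
    { "label": "f3", "intron_count": 6,
      "notes": "moss form; introns placed unlike the angiosperm classes" },
    { "label": "f4", "intron_count": 3, "phase_signature": [1, 0, 0],
      "notes": "dominant form: transit-peptide intron plus II_f and III_f" },
    { "label": "f5", "intron_count": 2, "phase_signature": [1, 0],
      "notes": "f4 lacking intron II_f" }
  ],
  "arrangements": [
    { "letter": "A", "category": "I",   "hop": "h1", "fus": "f1" },
    { "letter": "B", "category": "I",   "hop": "h2", "fus": "f1" },
    { "letter": "C", "category": "I",   "hop": "h3", "fus": "f2" },
    { "letter": "D", "category": "I",   "hop": "h4", "fus": "f3" },
    { "letter": "E", "category": "I",   "hop": "h4", "fus": "f4" },
    { "letter": "F", "category": "I",   "hop": "h5", "fus": "f4" },
    { "letter": "G", "category": "II",  "hop": "h5", "fus": "f4" },
    { "letter": "H", "category": "III", "hop": "h6", "fus": "f4" },
    { "letter": "I", "category": "III", "hop": "h5", "fus": "f4" },
    { "letter": "J", "category": "III", "hop": "h5", "fus": "f5" }
  ]
}
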