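{
  "comment": "Reference domain/motif residue ranges for human PARP-family proteins, transcribed from published results on AFDB models (AlphaFold DB version 2022-11-01). Only ranges quoted explicitly in text are marked approximate=false; other boundaries in the published overview figure are visual estimates and are not transcribed here.",
  "entries": {
    "PARP1_HUMAN": [
      {"label": "BRCT", "start": 383, "end": 525, "approximate": false,
       "note": "construct boundaries of the BRCT fragment used for NMR; includes part of the C-terminal linker"}
    ],
    "PARP4_HUMAN": [
      {"label": "PARP1-homology region", "start": 1, "end": 575, "approximate": false,
       "note": "N-terminal region close to PARP1 in domain composition: BRCT, WGR, HD, ART"},
      {"label": "MVPID", "start": 1570, "end": 1724, "approximate": false,
       "note": "all-helical major-vault-protein interacting domain; conserved patch around Arg1689"}
    ],
    "TNKS1_HUMAN": [
      {"label": "CHCC ZnF", "start": 1232, "end": 1246, "approximate": false,
       "note": "integrated zinc finger within the ART domain; a transformed ART loop, not a distinct subdomain"}
    ],
    "PARP6_HUMAN": [
      {"label": "C4*", "start": 284, "end": 330, "approximate": false,
       "note": "C4-type zinc finger with no homologue elsewhere; structurally distinct from the PARP1 C4 ZnF"}
    ],
    "PARP7_HUMAN": [
      {"label": "bridging helix", "start": 404, "end": 419, "approximate": false,
       "note": "wedged between ART and the first WWE of MZAP; part of the MZAP:ART rigid arrangement"},
      {"label": "ART C-terminal extension", "start": 651, "end": 657, "approximate": false,
       "note": "complements the beta-sheet of the first WWE domain"}
    ],
    "PARP8_HUMAN": [
      {"label": "C4*", "start": 503, "end": 552, "approximate": false,
       "note": "C4-type zinc finger rigidly connected to the split RWD"}
    ],
    "PARP10_HUMAN": [
      {"label": "ART", "start": 868, "end": 1025, "approximate": false,
       "note": "catalytic fragment used for nucleic-acid ADP-ribosylation assays"}
    ],
    "PARP14_HUMAN": [
      {"label": "KH1-KH2", "start": 316, "end": 468, "approximate": false,
       "note": "tandem KH fragment shown to bind single-stranded RNA"},
      {"label": "WWE-ART", "start": 1459, "end": 1801, "approximate": false,
       "note": "extended catalytic fragment; ADP-ribosylates terminally phosphorylated ssRNA/ssDNA"},
      {"label": "KH8-WWE-ART", "start": 1453, "end": 1801, "approximate": false,
       "note": "KH-extended catalytic fragment; binds RNA"}
    ]
  }
}
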