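{
  "elements": [
    {"name": "ABRE",     "consensus": "ACGTG",      "source_note": "ABA-responsive element core"},
    {"name": "HSE",      "consensus": "AGAANNTTCT", "source_note": "heat-shock element (inverted nGAAn repeat consensus)"},
    {"name": "ARE",      "consensus": "TGGTTT",     "source_note": "anaerobic-induction element"},
    {"name": "MBS",      "consensus": "CAACTG",     "source_note": "MYB binding site, drought inducibility"},
    {"name": "Box-W1",   "consensus": "TTGACC",     "source_note": "fungal elicitor responsive element (W-box)"},
    {"name": "TC-rich",  "consensus": "ATTTTCTTCA", "source_note": "defense and stress responsive repeat"}
  ]
}
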