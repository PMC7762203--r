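# Default cis-element definitions (IUPAC motifs; T and U equivalent).
# Sentinels: "G-RICH" = any g_window-long stretch with >= g_min G;
# "RICH:T" = any 6-nt stretch with >= 4 T (U-rich USE rule).
g_window: 6
g_min: 4
elements:
  USE:
    motifs: [TTTT]
    description: upstream sequence element (U-rich)
  UGUA:
    motifs: [TGTA]
    description: CFIm-recognized UGUA motif
  PAS:
    motifs: [AATAAA, ATTAAA]
    description: polyadenylation signal hexamer
  CS:
    motifs: [CA]
    description: cleavage after a CA dinucleotide
  DSE:
    motifs: [TTTTT, GTTGT]
    description: downstream sequence element (U/GU-rich)
  AuxDSE:
    motifs: [G-RICH]
    description: G-rich auxiliary DSE
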