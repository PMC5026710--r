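H CIDH920105
D Normalized average hydrophobicity scales (Cid et al., 1992)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.02   -0.42   -0.77   -1.04    0.77    -1.1   -1.14    -0.8    0.26    1.81
      1.14   -0.41       1    1.35   -0.09   -0.97   -0.77    1.71    1.11    1.13
//
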