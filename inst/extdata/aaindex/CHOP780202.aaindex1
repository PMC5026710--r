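H CHOP780202
D Normalized frequency of beta-sheet (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.83    0.93    0.89    0.54    1.19     1.1    0.37    0.75    0.87     1.6
       1.3    0.74    1.05    1.38    0.55    0.75    1.19    1.37    1.47     1.7
//
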