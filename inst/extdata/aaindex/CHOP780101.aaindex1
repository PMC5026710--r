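H CHOP780101
D Normalized frequency of beta-turn (Chou-Fasman, 1978a)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.66    0.95    1.56    1.46    1.19    0.98    0.74    1.56    0.95    0.47
      0.59    1.01     0.6     0.6    1.52    1.43    0.96    0.96    1.14     0.5
//
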