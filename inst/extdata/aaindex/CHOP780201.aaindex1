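H CHOP780201
D Normalized frequency of alpha-helix (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      1.42    0.98    0.67    1.01     0.7    1.11    1.51    0.57       1    1.08
      1.21    1.16    1.45    1.13    0.57    0.77    0.83    1.08    0.69    1.06
//
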