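H CHAM830101
D The Chou-Fasman parameter of the coil conformation (Charton-Charton, 1983)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.71    1.06    1.37    1.21    1.19    0.87    0.84    1.52    1.07    0.66
      0.69    0.99    0.59    0.71    1.61    1.34    1.08    0.76    1.07    0.63
//
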