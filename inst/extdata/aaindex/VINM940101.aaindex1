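H VINM940101
D Normalized flexibility parameters (B-values), average (Vihinen et al., 1994)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.984   1.008   1.048   1.068   0.906   1.037   1.094   1.031    0.95   0.927
     0.935   1.102   0.952   0.915   1.049   1.046   0.997   0.904   0.929   0.931
//
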