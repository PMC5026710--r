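H GEOR030101
D Linker propensity from all dataset (George-Heringa, 2003)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.964   1.143   0.944   0.916   0.778   1.047   1.051   0.835   1.014   0.922
     1.085   0.944   1.032   1.119   1.299   0.947   1.017   0.895       1   0.955
//
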