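aa	freq
Ala	0.0825
Arg	0.0553
Asn	0.0406
Asp	0.0545
Cys	0.0138
Gln	0.0393
Glu	0.0675
Gly	0.0707
His	0.0227
Ile	0.0596
Leu	0.0966
Lys	0.0584
Met	0.0242
Phe	0.0386
Pro	0.0470
Ser	0.0656
Thr	0.0534
Trp	0.0108
Tyr	0.0292
Val	0.0687
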