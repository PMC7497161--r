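aa	casp2	casp3
Gly	0.488	0.264
Ser	0.174	0.139
Ala	0.136	0.108
Met	0.059	0.033
Cys	0.030	0.045
Phe	0.023	0.047
Trp	0.018	0.020
Val	0.018	0.018
Tyr	0.017	0.060
Asn	0.012	0.081
His	0.009	0.031
Gln	0.005	0.009
Thr	0.004	0.032
Leu	0.004	0.019
Glu	0.003	0.011
Arg	NA	0.018
Lys	NA	0.008
Asp	NA	0.027
Ile	NA	0.020
Pro	NA	0.010
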