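p1prime	unmutated	unmutated_sd	D323T	D323T_sd	D323T_H226A	D323T_H226A_sd
Thr	180	12.0	58.0	16.4	42.4	6.8
Val	631.3	98.0	281.6	40.9	238.0	54.7
Ala	44.7	11.8	22.0	2.0	17.3	0.9
Ile	1269.3	343.5	529.3	75.1	494.4	134.8
Leu	400.0	117.6	296.9	64.9	165.1	54.3
Met	35.7	2.3	22.0	2.0	22.5	3.2
Ser	12.5	1.7	7.9	0.5	8.0	0.8
His	52.4	10.9	40.0	4.2	34.7	1.8
Cys	5.6	0.7	3.3	0.4	3.8	0.5
Arg	20.2	2.8	14.8	1.2	14.5	1.1
Asp	713.6	41.7	699.0	226.7	562.0	113.0
Gln	209.1	71.6	193.9	38.5	165.0	29.9
Glu	3010.3	805.8	2548.7	170.3	2400.0	145.1
Tyr	37.8	1.8	33.0	3.2	31.5	2.0
Phe	20.6	6.5	19.3	2.9	17.3	0.9
Trp	28.8	1.0	30.0	3.4	24.6	3.5
Asn	22.7	5.0	20.3	1.6	19.7	1.5
Lys	24.4	7.1	40.0	3.5	27.3	2.2
Gly	1	0	1	0	1	0
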