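path	step	mutation	ddg_ti	sd	ddg_raw
1	1	Asp323Thr	-7.5	0.8	-7.2
1	2	Val279Glu	11.7	4.0	9.9
1	3	Tyr284Phe	2.5	1.7	NA
1	4	His226Ala	-4.6	2.0	NA
2	1	His226Ala	-1.9	0.6	NA
2	2	Tyr284Phe	1.8	3.0	NA
2	3	Val279Glu	9.7	2.6	6.5
2	4	Asp323Thr	-6.9	4.3	-4.2
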