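path	step	mutation	ddg_bind	sd	ddg_raw	ddg_cat	ddg_cat_sd
1	1	Asp323Thr	-11.2	3.4	-11.0	3.7	2.3
1	2	His226Ala	-4.8	3.2	NA	0.2	2.7
2	1	His226Ala	-2.4	2.1	NA	0.5	1.6
2	2	Asp323Thr	-13.5	4.4	-13.3	6.6	4.1
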