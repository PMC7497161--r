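p1prime	enzyme	KM_uM	KM_ci	kcat	kcat_ci	efficiency
Ala	unmutated	89	11	7.1e-3	0.4e-3	80
Ala	D323T_H226A	57	23	1.2e-2	0.2e-2	214
Gly	unmutated	112	37	1.9e-1	0.3e-1	1720
Gly	D323T_H226A	55	13	2.5e-1	0.2e-1	4511
Ile	unmutated	71	25	9.3e-4	1.4e-4	13
Ile	D323T_H226A	67	18	2.7e-3	0.3e-3	40
Leu	unmutated	287	96	2.2e-3	0.5e-3	7.5
Leu	D323T_H226A	193	35	6.4e-3	0.7e-3	33
Pro	unmutated	305	146	8.1e-6	2.6e-6	0.026
Pro	D323T_H226A	43	23	1.6e-5	0.3e-5	0.37
Thr	unmutated	75	20	3.4e-3	0.4e-3	45
Thr	D323T_H226A	82	18	7.6e-3	0.8e-3	94
Val	unmutated	64	23	5.4e-4	0.8e-4	8.5
Val	D323T_H226A	77	14	2.6e-3	0.2e-3	34
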