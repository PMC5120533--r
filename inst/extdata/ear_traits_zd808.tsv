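stage	trait	unit	p1_mean	p1_sd	p2_mean	p2_sd	f1_mean	f1_sd
spikelet	ear_length	mm	6.4	0.36	8.25	1.07	15.58	0.69
spikelet	ear_diameter	mm	1.42	0.06	2.02	0.19	2.86	0.32
floret	ear_length	mm	10.3	1.15	14.23	0.55	20.67	1.53
floret	ear_diameter	mm	1.87	0.03	2.4	0.05	3.4	0.17
mature	ear_length	cm	15.05	0.26	20.28	1.00	26.05	0.58
mature	ear_diameter	cm	4.08	0.17	4.68	0.20	5.60	0.34
mature	ear_row_number	count	12.50	1.00	15.50	1.00	16	0.00
mature	kernel_number_per_row	count	21	1.15	32.25	1.71	50.75	4.03
mature	grain_yield	kg/mu	230	4.5	301	12.5	553	26.1
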