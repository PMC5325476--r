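quantity	PEP-I1	PEP-I2	PEP-I3	PEP-I4	PEP-II1	PEP-II2	PEP-II3
dG_interaction	-8.0	-6.8	-7.0	-6.3	-7.0	-8.3	-8.1
Kd_M	6.8e-06	1.1e-05	7.5e-06	4.4e-06	1.4e-06	8.2e-07	1.1e-06
ICs_ch_ch	4	4	6	2	5	5	5
ICs_ch_po	5	4	2	2	7	7	3
ICs_ch_ap	16	14	15	11	11	15	13
ICs_po_po	2	2	2	2	2	1	2
ICs_po_ap	4	2	4	7	4	6	4
ICs_ap_ap	13	15	13	16	15	18	16
NIS_ch_pct	27.54	28.99	28.17	30.54	29.52	30.32	29.80
NIS_ap_pct	38.42	38.65	39.44	36.95	38.10	33.84	35.86
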