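name	box	sequence	cluspro_score	instability_index	gravy	net_charge_ph7	water_solubility	aggregation_hotspot
Box-I-Initial	I	FQRGLLFPVCT	-822.2	66.03	0.836	0.9	Poor	No
PEP-I1	I	CQRGVWARVRC	-1340.2	-19.15	-0.282	2.9	Good	No
PEP-I2	I	CQRGWYGRVKC	-1159.9	-4.60	-0.927	2.9	Good	No
PEP-I3	I	CQRGQWYRVDC	-1217.3	-34.52	-1.173	0.9	Good	No
PEP-I4	I	CQRGFWGAVRC	-1133.1	-22.63	-0.036	1.9	Poor	Yes
Box-II-Initial	II	WELEPDGALDR	-733.6	5.17	-1.091	-3.0	Good	No
PEP-II1	II	WRKVQEGALDR	-1057.7	4.31	-1.355	1.0	Good	No
PEP-II2	II	WQKGKQGALDR	-1295.7	0.61	-1.718	2.0	Good	No
PEP-II3	II	WNRGRQGALDR	-1143.3	15.53	-1.827	2.0	Good	No
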