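group	pka	kind
Nterm	9.0	basic
Cterm	3.1	acidic
D	3.65	acidic
E	4.25	acidic
C	8.3	acidic
Y	10.1	acidic
H	6.0	basic
K	10.5	basic
R	12.0	basic
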