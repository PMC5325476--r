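resname	aa	class
ASP	D	charged
GLU	E	charged
LYS	K	charged
ARG	R	charged
HIS	H	charged
ASN	N	polar
GLN	Q	polar
SER	S	polar
THR	T	polar
TYR	Y	polar
ALA	A	apolar
CYS	C	apolar
PHE	F	apolar
GLY	G	apolar
ILE	I	apolar
LEU	L	apolar
MET	M	apolar
PRO	P	apolar
VAL	V	apolar
TRP	W	apolar
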