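# Aboderin (1971) amino-acid hydrophobicity scale (relative chromatographic
# mobility, 0-10). Loaded with hydrophobicity_scale(), which min-max
# normalizes the values to [0,1].
# residue	value
ALA	5.1
ARG	2.0
ASN	0.6
ASP	0.7
CYS	0.0
GLN	1.4
GLU	1.8
GLY	4.1
HIS	1.6
ILE	9.3
LEU	10.0
LYS	1.3
MET	8.7
PHE	9.6
PRO	4.9
SER	1.2
THR	2.7
TRP	9.2
TYR	8.0
VAL	8.5
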