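# SYNTHETIC stand-in amino-acid interface propensity table.
# Not the values of any specific published scale: the cited propensity
# source is not redistributable here.  The table reproduces the documented
# raw range (0 to 2.21) and the qualitative ordering common to
# protein-protein interface propensity scales: aromatic and large
# hydrophobic residues high, small/polar intermediate, charged and small
# residues low.  Override via pc_propensity_table(path = ...).
restype	propensity
TRP	2.21
PHE	1.95
MET	1.85
TYR	1.75
ILE	1.60
LEU	1.50
CYS	1.40
HIS	1.20
VAL	1.15
ARG	1.00
PRO	0.80
THR	0.70
ASN	0.65
GLN	0.60
ALA	0.55
SER	0.50
GLY	0.45
ASP	0.35
GLU	0.25
LYS	0.00
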