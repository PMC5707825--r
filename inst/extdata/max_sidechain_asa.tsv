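# Theoretical maximum side-chain solvent accessibility (A^2) per residue,
# computed with this package: extended Gly-X-Gly tripeptide (all chi = 180),
# Shrake-Rupley, probe 1.4 A, 960 points/atom, packaged vdW radii.
res	max_asa_A2
ALA	53.1
CYS	78.8
ASP	93.2
GLU	122.4
PHE	158.1
HIS	136.0
ILE	128.6
LYS	151.3
LEU	114.4
MET	140.4
ASN	98.2
PRO	104.9
GLN	127.3
ARG	186.6
SER	62.4
THR	90.7
VAL	104.6
TRP	191.9
TYR	168.7
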