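# Minimal embedded backbone-dependent rotamer library.
# Columns: res phi psi freq chi1..chi4 ("." = chi not defined for residue).
# Content: canonical side-chain chi modes with approximate literature
# frequencies, listed for two representative backbone bins (alpha-helix
# region phi/psi = -57/-47 and beta-sheet region -120/120). Intended for
# offline installs and testing; load a full-resolution library for
# production use. Coarse 30-degree binning is assumed by the default loader.
res	phi	psi	freq	chi1	chi2	chi3	chi4
SER	-57	-47	0.48	62	.	.	.
SER	-57	-47	0.29	-65	.	.	.
SER	-57	-47	0.22	180	.	.	.
CYS	-57	-47	0.50	-65	.	.	.
CYS	-57	-47	0.26	180	.	.	.
CYS	-57	-47	0.23	62	.	.	.
THR	-57	-47	0.49	62	.	.	.
THR	-57	-47	0.43	-65	.	.	.
THR	-57	-47	0.07	180	.	.	.
VAL	-57	-47	0.73	175	.	.	.
VAL	-57	-47	0.20	-60	.	.	.
VAL	-57	-47	0.06	64	.	.	.
ILE	-57	-47	0.60	-65	170	.	.
ILE	-57	-47	0.15	-57	-60	.	.
ILE	-57	-47	0.10	62	170	.	.
ILE	-57	-47	0.08	-177	170	.	.
LEU	-57	-47	0.59	-65	175	.	.
LEU	-57	-47	0.29	177	65	.	.
LEU	-57	-47	0.02	-85	65	.	.
PRO	-57	-47	0.45	28	-35	.	.
PRO	-57	-47	0.40	-28	35	.	.
MET	-57	-47	0.20	-65	-65	-70	.
MET	-57	-47	0.20	-67	177	75	.
MET	-57	-47	0.15	-67	177	-75	.
MET	-57	-47	0.12	-177	177	75	.
MET	-57	-47	0.10	-177	177	-75	.
MET	-57	-47	0.10	-67	177	180	.
ASP	-57	-47	0.51	-70	-15	.	.
ASP	-57	-47	0.23	-170	5	.	.
ASP	-57	-47	0.14	62	-10	.	.
ASN	-57	-47	0.30	-65	-40	.	.
ASN	-57	-47	0.25	-177	30	.	.
ASN	-57	-47	0.15	-65	120	.	.
ASN	-57	-47	0.10	62	-10	.	.
GLU	-57	-47	0.35	-67	180	-10	.
GLU	-57	-47	0.25	-177	177	0	.
GLU	-57	-47	0.15	-65	-75	-40	.
GLU	-57	-47	0.10	70	180	-20	.
GLN	-57	-47	0.38	-67	180	-25	.
GLN	-57	-47	0.20	-177	177	0	.
GLN	-57	-47	0.15	-65	-75	-40	.
GLN	-57	-47	0.08	70	180	20	.
LYS	-57	-47	0.25	-67	180	180	180
LYS	-57	-47	0.18	-177	180	180	180
LYS	-57	-47	0.10	-62	-68	180	180
LYS	-57	-47	0.08	-67	180	180	65
LYS	-57	-47	0.08	-67	180	180	-65
ARG	-57	-47	0.16	-67	180	180	180
ARG	-57	-47	0.12	-177	180	180	180
ARG	-57	-47	0.10	-67	180	65	85
ARG	-57	-47	0.08	-67	-167	-65	-85
ARG	-57	-47	0.06	62	180	180	180
HIS	-57	-47	0.29	-65	-70	.	.
HIS	-57	-47	0.14	-65	80	.	.
HIS	-57	-47	0.12	-177	-100	.	.
HIS	-57	-47	0.10	-177	60	.	.
HIS	-57	-47	0.09	62	-75	.	.
PHE	-57	-47	0.44	-65	-85	.	.
PHE	-57	-47	0.33	-177	80	.	.
PHE	-57	-47	0.13	62	90	.	.
TYR	-57	-47	0.43	-65	-85	.	.
TYR	-57	-47	0.34	-177	80	.	.
TYR	-57	-47	0.13	62	90	.	.
TRP	-57	-47	0.32	-65	95	.	.
TRP	-57	-47	0.18	-177	-105	.	.
TRP	-57	-47	0.15	-177	90	.	.
TRP	-57	-47	0.07	62	-90	.	.
SER	-120	120	0.45	62	.	.	.
SER	-120	120	0.32	-65	.	.	.
SER	-120	120	0.22	180	.	.	.
CYS	-120	120	0.52	-65	.	.	.
CYS	-120	120	0.26	180	.	.	.
CYS	-120	120	0.21	62	.	.	.
THR	-120	120	0.50	62	.	.	.
THR	-120	120	0.40	-65	.	.	.
THR	-120	120	0.09	180	.	.	.
VAL	-120	120	0.75	175	.	.	.
VAL	-120	120	0.18	-60	.	.	.
VAL	-120	120	0.06	64	.	.	.
ILE	-120	120	0.62	-65	170	.	.
ILE	-120	120	0.13	-57	-60	.	.
ILE	-120	120	0.11	62	170	.	.
ILE	-120	120	0.08	-177	170	.	.
LEU	-120	120	0.61	-65	175	.	.
LEU	-120	120	0.27	177	65	.	.
LEU	-120	120	0.02	-85	65	.	.
PRO	-120	120	0.50	28	-35	.	.
PRO	-120	120	0.35	-28	35	.	.
MET	-120	120	0.22	-65	-65	-70	.
MET	-120	120	0.20	-67	177	75	.
MET	-120	120	0.14	-67	177	-75	.
MET	-120	120	0.12	-177	177	75	.
MET	-120	120	0.10	-177	177	-75	.
MET	-120	120	0.09	-67	177	180	.
ASP	-120	120	0.48	-70	-15	.	.
ASP	-120	120	0.26	-170	5	.	.
ASP	-120	120	0.14	62	-10	.	.
ASN	-120	120	0.32	-65	-40	.	.
ASN	-120	120	0.24	-177	30	.	.
ASN	-120	120	0.14	-65	120	.	.
ASN	-120	120	0.10	62	-10	.	.
GLU	-120	120	0.36	-67	180	-10	.
GLU	-120	120	0.26	-177	177	0	.
GLU	-120	120	0.14	-65	-75	-40	.
GLU	-120	120	0.09	70	180	-20	.
GLN	-120	120	0.37	-67	180	-25	.
GLN	-120	120	0.22	-177	177	0	.
GLN	-120	120	0.14	-65	-75	-40	.
GLN	-120	120	0.08	70	180	20	.
LYS	-120	120	0.26	-67	180	180	180
LYS	-120	120	0.19	-177	180	180	180
LYS	-120	120	0.09	-62	-68	180	180
LYS	-120	120	0.08	-67	180	180	65
LYS	-120	120	0.08	-67	180	180	-65
ARG	-120	120	0.17	-67	180	180	180
ARG	-120	120	0.13	-177	180	180	180
ARG	-120	120	0.09	-67	180	65	85
ARG	-120	120	0.08	-67	-167	-65	-85
ARG	-120	120	0.06	62	180	180	180
HIS	-120	120	0.30	-65	-70	.	.
HIS	-120	120	0.13	-65	80	.	.
HIS	-120	120	0.13	-177	-100	.	.
HIS	-120	120	0.10	-177	60	.	.
HIS	-120	120	0.08	62	-75	.	.
PHE	-120	120	0.42	-65	-85	.	.
PHE	-120	120	0.35	-177	80	.	.
PHE	-120	120	0.13	62	90	.	.
TYR	-120	120	0.41	-65	-85	.	.
TYR	-120	120	0.36	-177	80	.	.
TYR	-120	120	0.13	62	90	.	.
TRP	-120	120	0.33	-65	95	.	.
TRP	-120	120	0.17	-177	-105	.	.
TRP	-120	120	0.16	-177	90	.	.
TRP	-120	120	0.07	62	-90	.	.
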