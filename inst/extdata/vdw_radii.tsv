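# Van der Waals radii for protein heavy atoms (Angstrom).
# Chothia/Tsai-family protein set, one radius per element; for carbon the
# carbonyl/aromatic value is used so that backbone carbonyl contacts seen
# in well-packed structures do not register as clashes.
# "*" is the fallback for unlisted elements.
element	radius_A
C	1.76
N	1.64
O	1.42
S	1.77
P	1.80
SE	1.90
*	1.80
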