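# Averaged backbone chemical shifts (ppm) per residue for the four nuclei
# used by the PseACS encoder: amide nitrogen (N15), alpha carbon (C13a),
# alpha proton (H1a) and amide proton (H1N).
# SYNTHETIC DEFAULT: these are representative stand-in values chosen to lie
# in the range of public BMRB averaged-shift statistics; they are NOT an
# official BMRB export and should be replaced via the acs_table config
# option when a calibrated table is available. PseACS lag features depend
# only on between-residue contrasts (they are invariant to a constant
# offset), so representative contrasts are what matters here.
# Note: proline has no amide proton; its H1N entry is a filler value so the
# table stays complete over 20 residues x 4 nuclei.
residue	N15	C13a	H1a	H1N
A	123.2	53.1	4.26	8.20
C	120.1	57.4	4.69	8.38
D	120.6	54.7	4.60	8.31
E	120.7	57.3	4.25	8.33
F	120.5	58.1	4.63	8.36
G	109.7	45.4	3.97	8.33
H	119.6	56.5	4.61	8.25
I	121.5	61.6	4.18	8.26
K	121.0	56.9	4.26	8.18
L	121.9	55.6	4.32	8.22
M	120.1	56.1	4.41	8.26
N	118.9	53.5	4.67	8.33
P	135.8	63.3	4.40	8.30
Q	119.9	56.6	4.27	8.21
R	120.8	56.8	4.30	8.23
S	116.3	58.7	4.47	8.31
T	115.5	62.2	4.45	8.24
V	121.1	62.5	4.16	8.29
W	121.7	57.7	4.66	8.29
Y	120.9	58.1	4.60	8.34
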