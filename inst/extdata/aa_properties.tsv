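# Per-residue physicochemical property table (20 standard amino acids x 9 properties).
# Provenance:
#   mass  - average molecular weight of the free amino acid (g/mol), standard tables
#   pk1   - alpha-carboxyl pKa; pk2 - alpha-amino pKa; pi - isoelectric point (standard tables)
#   hydrophobicity - Kyte & Doolittle hydropathy index
#   hydrophilicity - Hopp & Woods hydrophilicity scale
#   flexibility    - Bhaskaran & Ponnuswamy average flexibility index
#   rigidity       - constructed proxy: (max+min)-complement of the flexibility scale
#   irreplaceability - constructed proxy: 100 / Dayhoff relative mutability
# The rigidity and irreplaceability columns are constructed proxies (the scale this
# package is modeled on is not publicly reprinted); edit this file to substitute
# preferred scales. Encoders min-max scale each column over the 20 residues.
aa	rigidity	flexibility	irreplaceability	hydrophobicity	hydrophilicity	mass	pk1	pk2	pi
A	0.482	0.357	1.00	1.8	-0.5	89.09	2.34	9.69	6.00
R	0.310	0.529	1.54	-4.5	3.0	174.20	2.17	9.04	10.76
N	0.376	0.463	0.75	-3.5	0.2	132.12	2.02	8.80	5.41
D	0.328	0.511	0.94	-3.5	3.0	133.10	1.88	9.60	2.77
C	0.493	0.346	5.00	2.5	-1.0	121.16	1.96	10.28	5.07
Q	0.346	0.493	1.08	-3.5	0.2	146.15	2.17	9.13	5.65
E	0.342	0.497	0.98	-3.5	3.0	147.13	2.19	9.67	3.22
G	0.295	0.544	2.04	-0.4	0.0	75.07	2.34	9.60	5.97
H	0.516	0.323	1.52	-3.2	-0.5	155.16	1.82	9.17	7.59
I	0.377	0.462	1.04	4.5	-1.8	131.17	2.36	9.60	6.02
L	0.474	0.365	2.50	3.8	-1.8	131.17	2.36	9.60	5.98
K	0.373	0.466	1.79	-3.9	3.0	146.19	2.18	8.95	9.74
M	0.544	0.295	1.06	1.9	-1.3	149.21	2.28	9.21	5.74
F	0.525	0.314	2.44	2.8	-2.5	165.19	1.83	9.13	5.48
P	0.330	0.509	1.79	-1.6	0.0	115.13	1.99	10.96	6.30
S	0.332	0.507	0.83	-0.8	0.3	105.09	2.21	9.15	5.68
T	0.395	0.444	1.03	-0.7	-0.4	119.12	2.11	9.62	5.60
W	0.534	0.305	5.56	-0.9	-3.4	204.23	2.38	9.39	5.89
Y	0.419	0.420	2.44	-1.3	-2.3	181.19	2.20	9.11	5.66
V	0.453	0.386	1.35	4.2	-1.5	117.15	2.32	9.62	5.96
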