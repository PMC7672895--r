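# Per-residue physicochemical property scales used for the PseAAC and wavelet
# feature blocks. Columns:
#   hydrophobicity  - Kyte & Doolittle hydropathy index
#   hydrophilicity  - Hopp & Woods hydrophilicity
#   flexibility     - Bhaskaran & Ponnuswamy average flexibility index
#   asa             - Rose et al. mean standard-state accessible surface area (A^2)
#   sidechain_mass  - monoisotopic side-chain mass (residue mass minus backbone C2H2NO)
residue	hydrophobicity	hydrophilicity	flexibility	asa	sidechain_mass
A	1.8	-0.5	0.357	118.1	15.02347
R	-4.5	3.0	0.529	256.0	100.08747
N	-3.5	0.2	0.463	165.5	58.02929
D	-3.5	3.0	0.511	158.7	59.01330
C	2.5	-1.0	0.346	146.1	46.99555
Q	-3.5	0.2	0.493	193.2	72.04494
E	-3.5	3.0	0.497	186.2	73.02895
G	-0.4	0.0	0.544	88.1	1.00782
H	-3.2	-0.5	0.323	202.5	81.04527
I	4.5	-1.8	0.462	181.0	57.07042
L	3.8	-1.8	0.365	193.1	57.07042
K	-3.9	3.0	0.466	225.8	72.08132
M	1.9	-1.3	0.295	203.4	75.02685
F	2.8	-2.5	0.314	222.8	91.05477
P	-1.6	0.0	0.509	146.8	41.03912
S	-0.8	0.3	0.507	129.8	31.01839
T	-0.7	-0.4	0.444	152.5	45.03404
W	-0.9	-3.4	0.305	266.3	130.06567
Y	-1.3	-2.3	0.420	236.8	107.04969
V	4.2	-1.5	0.386	164.5	43.05477
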