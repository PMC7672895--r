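# Ten disjoint side-chain chemistry classes covering the 20-letter alphabet.
# Order fixes the layout of the group-frequency (10) and group-transition (45)
# feature blocks; C(10,2) = 45.
index	name	residues
1	glycine	G
2	aliphatic	AVLI
3	hydroxyl	ST
4	cysteine	C
5	methionine	M
6	proline	P
7	aromatic	FWY
8	amide	NQ
9	acidic	DE
10	basic	KRH
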