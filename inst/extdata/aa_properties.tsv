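code	name	mw_g_mol	volume_A3	hydrophobicity_ph7
A	Alanine	89.09	88.6	41
R	Arginine	174.20	173.4	-14
N	Asparagine	132.12	114.1	-28
D	Aspartate	133.10	111.1	-55
C	Cysteine	121.16	108.5	49
Q	Glutamine	146.15	143.8	-10
E	Glutamate	147.13	138.4	-31
G	Glycine	75.07	60.1	0
H	Histidine	155.15	153.2	8
I	Isoleucine	131.17	166.7	99
L	Leucine	131.17	166.7	97
K	Lysine	146.19	168.6	-23
M	Methionine	149.21	162.9	74
F	Phenylalanine	165.19	189.9	100
P	Proline	115.13	112.7	-46
S	Serine	105.09	89.0	-5
T	Threonine	119.12	116.1	13
W	Tryptophan	204.23	227.8	97
Y	Tyrosine	181.19	193.6	63
V	Valine	117.15	140.0	76
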