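tf_symbol	k_dysregulated_targets	p_value	neglog10_p
foxc1a	207	0.0000	4.9689
foxa2	97	0.0001	3.8315
zic3	21	0.0006	3.2427
maza	23	0.0011	2.9524
rarab	48	0.0016	2.7962
elf3	69	0.0019	2.7307
hnf4a	44	0.0034	2.4676
atf7b	21	0.0153	1.8144
cdx4	58	0.0234	1.6299
cebpg	9	0.0312	1.5052
myb	16	0.0391	1.4078
maf	16	0.0454	1.3426
irf11	25	0.0537	1.2701
sox9b	27	0.0540	1.2679
nr3c1	14	0.0546	1.2631
sox2	52	0.0567	1.2465
tfa	3	0.0739	1.1315
pitx2	26	0.0793	1.1008
arntl2	17	0.0952	1.0215
mycn	4	0.1035	0.9852
zbtb12	10	0.1105	0.9568
hdx	11	0.1218	0.9143
mnta	4	0.1541	0.8121
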