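gene_symbol	fold_change	p_value	pwm_available
tfa	-2.05	0.0016	TRUE
sox2	-1.99	0.0001	TRUE
elf3	-1.87	0.0003	TRUE
si:ch211-222e23.7	-1.78	0.0032	TRUE
cdx4	-1.62	0.0048	TRUE
pitx2	-1.62	0.0284	TRUE
maf	-1.47	0.0015	TRUE
foxc1a	-1.43	0.0002	TRUE
zic3	-1.32	0.0063	TRUE
foxa2	-1.31	0.0132	TRUE
hnf4a	-1.30	0.0155	TRUE
gata6	-1.26	0.0052	TRUE
LOC797948	1.28	0.0222	TRUE
atf7b	1.27	0.0082	TRUE
mycn	1.30	0.0100	TRUE
arntl2	1.32	0.0022	TRUE
rarab	1.36	0.0101	TRUE
mycb	1.37	0.0076	TRUE
cebpg	1.41	0.0082	TRUE
wu:fb82f02	1.46	0.0070	TRUE
maza	1.50	0.0219	TRUE
myb	1.57	0.0003	TRUE
nr3c1	1.70	0.0053	TRUE
sox9b	1.72	0.0005	TRUE
irf11	1.84	0.0030	TRUE
her7	-2.93	0.0003	FALSE
msgn1	-2.35	0.0012	FALSE
her1	-2.10	0.0126	FALSE
zgc:136639	-1.83	0.0026	FALSE
sp5l	-1.82	0.0014	FALSE
otx1a	-1.69	0.0138	FALSE
irx1b	-1.56	0.0193	FALSE
irx3a	-1.49	0.0119	FALSE
nr0b2a	-1.46	0.0011	FALSE
eve1	-1.41	0.0004	FALSE
pknox1.1	-1.39	0.0005	FALSE
hes6	-1.35	0.0062	FALSE
lhx1a	-1.34	0.0123	FALSE
msxb	-1.34	0.0091	FALSE
nr0b2a	-1.32	0.0045	FALSE
sp5	-1.27	0.0186	FALSE
LOC407678	1.26	0.0141	FALSE
etv5a	1.26	0.0235	FALSE
zgc:162349	1.27	0.0002	FALSE
zgc:165515	1.27	0.0058	FALSE
zgc:162349	1.27	0.0009	FALSE
zorba	1.28	0.0237	FALSE
zhx3	1.30	0.0050	FALSE
si:rp71-1g18.1	1.30	0.0134	FALSE
znf277	1.30	0.0185	FALSE
lrrfip1a	1.33	0.0045	FALSE
si:ch211-119o8.6	1.33	0.0086	FALSE
lrrfip2	1.35	0.0099	FALSE
her5	1.36	0.0023	FALSE
rcor2	1.37	0.0075	FALSE
pias4l	1.38	0.0259	FALSE
terf1	1.46	0.0108	FALSE
klf2a	1.46	0.0034	FALSE
LOC100149164	1.48	0.0037	FALSE
etv5a	1.48	0.0261	FALSE
si:dkeyp-68b7.7	1.50	0.0046	FALSE
LOC797322	1.66	0.0283	FALSE
tsc22d2	1.96	0.0028	FALSE
zgc:77060	2.51	0.0109	FALSE
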