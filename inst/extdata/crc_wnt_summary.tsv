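feature	type	tumor_mean	normal_mean	printed_fc
CSNK2A2	gene	46.72	23.14	2.02
PLCB4	gene	325.61	166.3	1.96
SFRP4	gene	35.37	5.03	7.03
CCND1	gene	317.79	122.64	2.59
SFRP5	gene	0.67	1.23	0.54
RAC2	gene	22.11	37.39	0.59
ROCK2	gene	447.77	282.59	1.58
MYC	gene	181.11	49	3.7
PLCB2	gene	31.51	56.18	0.56
DAAM2	gene	23.25	52.19	0.45
PRICKLE2	gene	30.26	50.46	0.6
PRKCB	gene	14.65	53.12	0.28
CTNNB1	gene	581.34	358	1.62
hsa-miR-20b-5p	mirna	17.65	3.3	5.35
hsa-miR-650	mirna	4.51	16.6	0.27
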