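proteome	c.1.1	c.2.1	c.3.1	c.4.1	c.5.1	c.6.1
p001	26	20	0	16	16	0
p002	17	19	0	12	14	0
p003	23	17	0	21	11	0
p004	27	22	0	17	0	6
p005	12	21	0	0	0	0
p006	23	14	0	0	13	6
p007	0	0	6	17	12	10
p008	21	21	0	15	0	0
p009	19	0	0	19	7	9
p010	0	16	0	14	10	0
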