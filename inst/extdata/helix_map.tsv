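taxon	h1.S1	h1.H1	h1.S1'	h2.S1	h2.H1	h2.S1'	h3.S1	h3.H1	h3.S1'	h4.S1	h4.H1	h4.S1'	h5.S1	h5.H1	h5.S1'	h6.S1	h6.H1	h6.S1'
taxon1	20	4	20	4	4	4	24	4	24	16	4	16	8	4	8	11	4	11
taxon2	21	4	21	3	4	3	24	4	24	17	4	17	8	4	8	12	4	12
taxon3	20	4	20	3	4	3	24	4	24	17	4	17	8	4	8	12	4	12
taxon4	20	4	20	3	4	3	24	4	24	17	4	17	8	4	8	12	4	12
taxon5	20	4	20	4	4	4	24	4	24	16	4	16	9	4	9	11	4	11
taxon6	20	4	20	4	4	4	24	4	24	16	4	16	8	4	8	11	4	11
taxon7	20	4	20	4	4	4	24	4	24	17	4	17	8	4	8	12	4	12
taxon8	20	4	20	4	4	4	24	4	24	17	4	17	8	4	8	12	4	12
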