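domain	age	birth_rank
c.1.1	0.9148060434963554	2
c.2.1	0.9370754132978618	1
c.3.1	0.2861395347863436	6
c.4.1	0.8304476260673255	3
c.5.1	0.6417455188930035	4
c.6.1	0.5190959491301328	5
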