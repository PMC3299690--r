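helix	birth_rank	baseline_stem
h1	2	20
h2	6	4
h3	1	24
h4	3	16
h5	5	8
h6	4	12
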