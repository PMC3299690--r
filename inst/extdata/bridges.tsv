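id	class	acceptor	donor
B1	bridge	h1	h2
B2	bridge	h3	h5
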