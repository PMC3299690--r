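(((taxon2,taxon3),((taxon7,taxon8),taxon4)),(taxon1,(taxon5,taxon6)));
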