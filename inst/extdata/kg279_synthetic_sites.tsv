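residue	site
396	cavity
408	cavity
415	cavity
423	cavity
425	cavity
457	cavity
458	surface
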