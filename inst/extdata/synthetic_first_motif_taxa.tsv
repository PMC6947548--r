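metazoa_A	Metazoa
metazoa_B	Metazoa
bacteria_A	Bacteria
bacteria_B	Bacteria
fungi_A	Fungi
fungi_B	Fungi
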