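term	id
HTR1B	HTR1B
CYP1A2	CYP1A2
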