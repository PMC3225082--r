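gene	disease	provenance
HTR1B	Autistic_Disorder	pubmedid19038234
CYP1A2	Lymphoma	
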