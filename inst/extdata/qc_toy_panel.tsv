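s01	HL
s02	HL
s03	HL
s04	HL
s05	HL
s06	LL
s07	LL
s08	LL
s09	LL
s10	LL
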