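CSF_CIRCULATION	GO:0090660 synthetic stand-in	Aqp4	Slc4a4	Slc6a11	Cldn10	Nkain4	Kcnk1
MITO_RESPIRASOME	GO:0005746 synthetic stand-in	Bg05	Bg09	Bg12	Bg17	Bg21	Bg26
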