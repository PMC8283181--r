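generic	brands	target
nivolumab	Opdivo	PD-1
pembrolizumab	Keytruda	PD-1
cemiplimab	Libtayo	PD-1
atezolizumab	Tecentriq	PD-L1
avelumab	Bavencio	PD-L1
durvalumab	Imfinzi	PD-L1
ipilimumab	Yervoy	CTLA-4
tremelimumab		CTLA-4
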