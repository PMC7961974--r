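SRC	L	+1
SRC	R	+1
L	SINK	+1
R	SINK	+1
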