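name	isb	sex	species
Dinah	356	female	B
Billy	590	male	B
Dolly	364	female	B
Dennis	360	male	B
Louis	990	male	B
Likoe	1600	male	S
Baldy	732	male	S
Doris	53	female	S
Sibu	550	female	S
Bubbles	695	female	T
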