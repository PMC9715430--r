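time_ka	source	dest	fraction
8	WHG	MAIN	0.50
4.5	STP	MAIN	0.33
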