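population	branch	time_ka	n
AnatolianEF	MAIN	8.5	28
WHG	WHG	8.5	45
Steppe	STP	5	68
EF	MAIN	7	78
LNBA	MAIN	4	192
ModernEuropeans	MAIN	0	200
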