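name	Ne	start_ka	end_ka	parent
ANC	22800	66	65	NA
AFR	22800	65	0	ANC
OOA	1900	65	55	ANC
MAIN	12000	55	0	OOA
STP	6000	45	4.5	MAIN
WHG	2000	40	8	MAIN
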