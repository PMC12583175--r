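from	to	enzyme	authenticated
phenylalanine	cinnamic acid	PAL	TRUE
tyrosine	p-coumaric acid	TAL	TRUE
cinnamic acid	p-coumaric acid	C4H	TRUE
p-coumaric acid	caffeic acid	C3H	TRUE
caffeic acid	ferulic acid	OMT	TRUE
p-coumaric acid	2,4-dihydroxy-cinnamic acid	C2'H	TRUE
2,4-dihydroxy-cinnamic acid	umbelliferone	COSY	TRUE
ferulic acid	scopoletin	F6'H	TRUE
umbelliferone	esculetin	F6'H	FALSE
esculetin	scopoletin	OMT	FALSE
scopoletin	scopolin	2GT	TRUE
scopoletin	fraxetin	S8H	TRUE
fraxetin	isofraxidin	OMT	TRUE
scopoletin	6,7-dimethoxycoumarin	OMT	FALSE
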