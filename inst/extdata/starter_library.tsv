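name	formula	class	subclass	source	score
scopoletin	C10H8O4	coumarin	hydroxycoumarin	literature	NA
isofraxidin	C11H10O5	coumarin	hydroxycoumarin	literature	NA
scopolin	C16H18O9	coumarin	coumarin_glycoside	literature	NA
fraxetin	C10H8O5	coumarin	hydroxycoumarin	literature	NA
umbelliferone	C9H6O3	coumarin	hydroxycoumarin	literature	NA
esculetin	C9H6O4	coumarin	hydroxycoumarin	literature	NA
6,7-dimethoxycoumarin	C11H10O4	coumarin	methoxycoumarin	literature	NA
chimsalicifoliusin A	C21H16O9	coumarin	bicoumarin	literature	NA
chimsalicifoliusin B	C20H14O8	coumarin	bicoumarin	literature	NA
3,3'-biisofraxidin	C22H18O10	coumarin	bicoumarin	literature	NA
arteminorin A	C20H14O8	coumarin	bicoumarin	literature	NA
cinnamic acid	C9H8O2	cinnamic_acid	cinnamic_acid	literature	NA
p-coumaric acid	C9H8O3	cinnamic_acid	hydroxycinnamic_acid	literature	NA
caffeic acid	C9H8O4	cinnamic_acid	hydroxycinnamic_acid	literature	NA
ferulic acid	C10H10O4	cinnamic_acid	methoxycinnamic_acid	literature	NA
sinapinic acid	C11H12O5	cinnamic_acid	methoxycinnamic_acid	literature	NA
luteoloside	C21H20O11	flavonoid	flavone_glycoside	literature	NA
quercitrin	C21H20O11	flavonoid	flavonol_glycoside	literature	NA
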