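category	gene
identity	INS
identity	IAPP
identity	HADH
ion flux	ABCC8
ion flux	KCNJ6
ion flux	KCNK16
ion flux	KCTD12
glucose metabolism	ACLY
glucose metabolism	PKM
glucose metabolism	G6PC2
glucose metabolism	GPX3
glucose metabolism	GSTA4
vesicle trafficking	VAMP2
vesicle trafficking	SYT7
exocytosis	PCLO
exocytosis	TSPAN7
exocytosis	RGS9
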