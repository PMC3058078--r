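name	pattern	factors	response
ACGT	ACGT	bZIP/PIF/bHLH	ABA (ABRE), light (G box), biotic stress
DRE	CCGAC	DREB1/2 (ERF/AP2)	cold, drought
CGCG	CGCG	AtSR	various stresses
Myc	CANNTG	Myc	ABA
Dof	AAAG	Dof	various regulation
GCCCA	GCCCA	TCP	meristematic expression
H box	CCTACC	MYB	biotic stress
W box	TTGAC(C/T)	WRKY	biotic stress, ABA, senescence
AACCGG	AACCGG	unknown
AuxRE	TGTCTC	ARF	auxin
GCC box	AGCC(A/G)CC	ERF/AP2	ethylene, biotic stress
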