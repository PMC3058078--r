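reg_id	octamer	ABA	Ethylene	BL	CK	Auxin	JA	SA	H2O2	Drought	DREB1Aox	annotation
AtREG366	CACGTGTC	9.132	0	0	0.344	0	0	0	0.492	2.747	2.631	ABA
AtREG367	CACGTGGC	6.309	0	0	0.363	0	0	0	0	2.204	2.462	ABA
AtREG371	ACGTGGCG	6.427	0	0	0	0	0	0	0	2.066	0	ABA
AtREG379	ACGTGGCA	3.464	0	0	0	0	0	0	0	1.765	2.959	ABA
AtREG382	ACACGTGG	7.351	0	0	0	0	0	0	0	2.671	0	ABA
AtREG389	ACGTGTCA	5.964	0	0	0	0	0	0	0	2.069	2.255	ABA
AtREG404	CCCGGCCC	0	0	0	4.197	0	0	0	0	0	0	CK
AtREG408	CACGTGGA	6.095	0	0	0	0	0	0	0	2.406	0	ABA
AtREG428	ACGACACG	5.324	3.294	0	0	0	2.283	0	0	3.203	3.579	ABA, DREB1Aox, Ethylene, Drought
AtREG438	ATGACACG	3.409	0	0	0	0	0	0	0	0	0	ABA
AtREG440	CACGTCAG	4.46	0	0	0	0	0	0	0	0	0	ABA
AtREG441	AACCGCGT	0	0	0	0	0	0	0	2.6	3.969	0	Drought
AtREG446	ATTGGCCC	0	0	0	3.137	0	0	0	0	0	0	CK
AtREG448	ATGCCACG	3.538	0	0	0	0	0	0	0	1.779	4.892	ABA, DREB1Aox
AtREG450	ACGTGGCT	3.3	0	0	0	0	0	0	0	0	0	ABA
AtREG453	CACGTGTA	5.469	0	0	0	0	2.59	0	0	2.355	4.812	ABA, DREB1Aox
AtREG457	CCGGCCCA	0	0	0	4.458	0	0	0	0	0	0	CK
AtREG460	CACACGTG	5.438	0	0	0	0	0	0	0	1.963	3.07	ABA, DREB1Aox
AtREG464	CACGTGGG	3.333	0	0	0	3.9	3.086	0	0	0	0	ABA, Auxin, JA
AtREG466	CACGTCAC	3.689	0	0	0	0	0	0	0	0	0	ABA
AtREG468	CGTGGCAG	3.422	0	0	0	0	0	0	0	0	0	ABA
AtREG470	ACGTGTCT	5.361	0	0	0	0	0	0	0	1.964	0	ABA
AtREG471	CGTGGCGA	6.784	0	0	0	0	0	0	0	0	0	ABA
AtREG472	ACGTGTCC	11.95	0	0	0	0	0	0	0	3.235	4.6	ABA, DREB1Aox, Drought
AtREG478	ACGTGTCG	10.48	0	0	0	0	2.285	0	0	3.577	4.41	ABA, DREB1Aox, Drought
AtREG481	GACACGTC	5.088	0	0	0	0	0	0	0	0	0	ABA
AtREG488	CCGCGTTA	0	0	0	0	0	0	4.104	0	2.792	0	SA
AtREG489	ACGTCACG	4.287	0	0	0	0	0	0	0	0	4.15	ABA, DREB1Aox
AtREG498	CGTGTCAC	4.889	0	0	0	0	0	0	0.205	2.059	0	ABA
AtREG502	CCGCGTGA	0	0	0	0	0	0	0	0	3.834	0	Drought
AtREG513	ACGTGGAC	3.018	0	0	0	0	0	0	0	0	3.652	ABA, DREB1Aox
AtREG515	ACGTCAGC	2.858	0	0	0	0	0	3.413	0	0	0	SA
AtREG517	ACACGTCA	5.332	0	0	0	0	0	0	0	0	0	ABA
AtREG527	AACGACAC	0	0	0	0	0	0	0	0	0	3.122	DREB1Aox
AtREG536	ACACGCGT	6.784	0	0	0	0	0	0	0	3.214	0	ABA, Drought
AtREG544	ACCACGTG	4.347	0	0	0	0	0	0	0	2.484	3.506	ABA, DREB1Aox
AtREG547	ACGTGGAT	3.101	0	0	0	0	0	0	0	1.679	0	ABA
AtREG553	CAACGGTC	0	0	0	0	5.769	0	0	0	0	0	Auxin
AtREG557	GACACGTA	8.185	0	2.877	0	0	0	0	0	2.998	4.66	ABA, DREB1Aox
AtREG560	CCGCCACG	4.988	0	0	0	0	0	0	0	0	0	ABA
AtREG562	ACGTGTAC	4.064	0	0	0	3.303	0	0	0	1.956	0	IN tabl
AtREG578	ACGTCATC	3.34	0	0	0	0	0	1.994	0	0	0	ABA
AtREG588	ACGTGTGA	3	0	0	0	0	0	0	0	0	2.722	ABA
AtREG590	AACACGTG	7.004	0	0	0	0	3.541	0.36	0	2.942	0	ABA, JA
AtREG595	ACCCCTGA	0	0	0	3.817	0	0	0	0	0	0	CK
AtREG606	ACGTGACA	3.205	0	0	0	0	1.855	2.391	0	0	0	ABA
AtREG608	AAGCCACG	3.053	0	0	0	0	0	0	0	0	0	ABA
AtREG612	GGCCCACA	0	0	0	2.858	0	0	0	0	0	3.327	DREB1Aox
AtREG615	GGGACCCA	4.26	0	0	0	0	0	0	0	0	0	ABA
AtREG628	ACACGTGA	2.672	0	0	0	0	2.835	0	1.888	1.899	3.637	DREB1Aox
AtREG631	CGCGTGAA	0	0	0	0	0	0	0	0	3.332	0	Drought
AtREG638	AGTCGGTC	5.571	0	0	0	0	0	2.771	0	0	9.436	DREB1Aox, ABA
AtREG646	CGTAATTA	3.016	0	0	0	0	0	0	0	0	0	ABA
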