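record_id	table_kind	gene_symbols	aliases	cleft_type	penetrance_note	pmids	note
T1-01	single	Bmp4		CLO		15716346	Nestin-Cre;Bmp4 F/n cKO mice show unilateral CL.
T1-02	single	Bmpr1a		CLP		15716346	Nestin-Cre;Bmpr1a cKO mice show bilateral CL and CP.
T1-03	single	Cdc42		CLP or CPO	CL at 10% and CP at 100%	24056078	Wnt1-Cre;Cdc42 cKO mice show either unilateral or bilateral CL.
T1-04	single	Clpex		midfacial cleft and CLP		21515572	Homozygous mutant mice show several types of facial clefting and CP.
T1-05	single	Cplane1		CLP		25877302	Homozygous mutant mice show CL and CP.
T1-06	single	Cplane2 (aka Rsg1)		CLO		25807483	Homozygous mutants show CL. ENU-induced point mutation.
T1-07	single	Ctnnb1		CLP		22354888	Pitx1-Cre;Ctnnb1 gain- and loss-of-function cKO mice show CL and CP.
T1-08	single	Dzip1l		CLP		28530676	Homozygous null mutant mice show bilateral CL and CP.
T1-09	single	Ednrb		CLP or CPO	CL at 27% and CP at 83%	8722795;17693063	Homozygous null mutant mice.
T1-10	single	Ermp1		CLP		25807483	Homozygous mutant mice show CL and CP. ENU-induced point mutation.
T1-11	single	Esrp1		CLP	CL and CP at 100%	26371508	Homozygous null mutant mice.
T1-12	single	Ext1		CLP		19509472	Wnt1-Cre;Ext1 cKO mice show CL and CP.
T1-13	single	Folr1 (aka Folbp1)		CLP or CLO	bilateral CL at 43%, unilateral CL at 32%, CP at 51%	12854656	Homozygous null mutant mice; some embryos show mandibular cleft.
T1-14	single	Gldc		midfacial cleft or CLP		25807483	Homozygous mutant mice show midfacial cleft or CL and CP. ENU-induced point mutation.
T1-15	single	Kif7		CLO, CLP, or CPO		25807483	Homozygous mutant mice show CL or CP. ENU-induced point mutation.
T1-16	single	Lgl		CLP or midfacial cleft and CP	midfacial cleft or CL and CP at 40%	3406741;2313245	Lgl Tg/Tg deletion transgenic mice.
T1-17	single	Lrp6		CLP	CL and CP at 100%	19700620;19653321	Homozygous null mutant mice show either bilateral or unilateral CL.
T1-18	single	Mirc1 (aka miR-17-92)		CLP	bilateral CL/P at 32.4% and unilateral CL/P at 17.7%; mandibular cleft at 44%	24068957	Homozygous null mutant mice.
T1-19	single	Mks1		CLO, CLP, or CPO		21045211;23454480	Homozygous null mutant mice show CL and/or CP.
T1-20	single	Myh10		CLO		25807483	Homozygous mutant mice show CL. ENU-induced point mutation.
T1-21	single	Nosip		CLP, midfacial cleft and CP	unilateral CL and CP at 48.6%; midfacial cleft with CP at 28.6%	25546391	Nosip null mice.
T1-22	single	Pbx1		CLO, CLP, or CPO	CPO at 33%, CL and CP at 62%, unilateral CLO at 5%	29797482	Foxg1-Cre;Pbx1 cKO mice.
T1-23	single	Ph		midfacial cleft, CLO, or CLP			Patch deletion region; homozygous mutant mice show facial cleft or CL. Reference Mouse Genome 92(3):504-505.
T1-24	single	Porcn		CLO or CLP	CL at 100%	25451153	Wnt1-Cre and Rx3-Cre Porcn F/Y cKO mice show CL and CP.
T1-25	single	Ptch1		CL or midfacial cleft		23900075	Wnt1-Cre;Ptch1 cKO embryos at E12.5; embryos die by E12.5.
T1-26	single	Ptpn11		CLP	CL and CP at 21%	19706403	Wnt1-Cre;Ptpn11 Tg/+ gain-of-function mice.
T1-27	single	Rpgrip1l		CLO		17553904;17558409;21677750	Homozygous null mutant mice show CL.
T1-28	single	Satb2		CLP		16960803;16751105	Homozygous null mutant mice show CL and CP.
T1-29	single	Sox11		CLP or CPO	CL at 70% and CP at 100%	15254231;26826126	Homozygous null and EIIa-Cre;Sox11 cKO mice.
T1-30	single	Sp8		CLO	5 out of 13	23872235	FoxG1-Cre;Sp8 cKO mice exhibit CLO.
T1-31	single	Tbc1d32		CLO or CLP		25807483	Homozygous mutant mice show CL and CP. ENU-induced point mutation.
T1-32	single	Tbx1		CLO or CLP		19557177	Conditional Tbx1 overexpression mice exhibit bilateral CL; rescued by Smad1 overexpression.
T1-33	single	Tfap2a		CLP	CL and CP at 100%	25381013	Tfap2a null/neo mice show bilateral CL.
T1-34	single	Tgfbr1 (aka Alk5)		CLO or CLP	CL at 64%	18586087	Nestin-Cre;Tgfbr1 cKO mice; no information about CP.
T1-35	single	Tmem107		CLP	CL and CP at 14%	22698544;28954202	Homozygous mutant mice.
T1-36	single	Trp53		CLP		25119037	CMV-Cre;Trp53 conditional mice show CL and CP.
T1-37	single	Trp63		CLP	CL and CP at 100%	18634775	Homozygous null mutant mice show bilateral CL.
T1-38	single	Wdr19 (aka Ift144)		CLP		22228095	Homozygous mutant mice show bilateral CL and CP. ENU-induced point mutation.
T1-39	single	Wnt9b		CLO or CLP	bilateral CL at 59%	21982646	Foxg1-Cre;Wnt9b cKO mice show CP.
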