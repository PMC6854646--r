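record_id	table_kind	gene_symbols	aliases	cleft_type	penetrance_note	pmids	note
T2-01	spontaneous	Clf2		CLP		7601909	Homozygous mutant mice show CL and CP at higher incidence.
T2-02	spontaneous	Rpl38		CLO, CLP, or CPO		10889952;21529712	Heterozygous mutant mice show CL and/or CP.
T2-03	spontaneous	Tbx10		CLP		5297683;15118109	Homozygous Tbx10 Tg/Tg gain-of-function mice show unilateral or bilateral CL and CP.
T2-04	spontaneous	Wnt9b (aka Clf1)		CLO or CLP		16998816	Homozygous null mutant mice show unilateral or bilateral CL with/without CP.
T2-05	spontaneous	Zeb1		CLP		13539273;10669096	Twirler line; unilateral or bilateral, complete or incomplete CL and CP.
T2-06	spontaneous			CLO or CLP	10% mice show CL/P	7202260	Not gene; strain A/HeJ.
T2-07	spontaneous			CLO or CLP	10% mice show CL/P	7202260;7394720	Not gene; strain A/J.
T2-08	spontaneous			CLO or CLP	20-30% mice show CL/P	7202260	Not gene; strain A/Wysn.
T2-09	spontaneous			CLO or CLP	20-40% mice show CL/P; the cleft frequency depends on the colony	5538410;7102571;7394720	Not gene; strain CL/Fr.
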