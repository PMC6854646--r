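record_id	table_kind	gene_symbols	aliases	cleft_type	penetrance_note	pmids	note
T3-01	compound	Bbs7;Ift88		CLO or CLP		22228099	Bbs7-/-;Ift88 orpk double mutants exhibit CL at E12.5; single mutants show neither CL nor CP.
T3-02	compound	Fgf8;Tfap2a		CLP	bilateral CL and CP in 10/18 and unilateral CL/P in 8/10	25381013	Tfap2a null/neo;Fgf8 +/- rescue model of Tfap2a null/neo mice.
T3-03	compound	Gdf1;Nodal		CLO	CL at 68% at E13.5	16564040	Gdf1-/-;Nodal+/- mutant mice.
T3-04	compound	Hhat;Ptch1		CLP		24590292	Double heterozygous mice show CL and primary palate cleft at E12.5.
T3-05	compound	Lrp6;Rspo2		CLP or CPO	CL and CP in 1/6 or CPO in 5/6	21237142	Lrp6+/-;Rspo2-/- mutant mice.
T3-06	compound	Mirc1;Mirc3	Mirc1=miR-17-92;Mirc3=miR-106b-25	CLP	bilateral CL and CP in 100% and mandibular cleft at 100%	24068957	Mirc1 null;Mirc3 null and Mirc1 null;Mirc3 het mutant mice.
T3-07	compound	Msx1;Pax9		CLP or CPO	unilateral or bilateral CL at 39%, CP and midfacial hypoplasia at 100%	20123092	Msx1-/-;Pax9-/- double KO mice.
T3-08	compound	Pbx1;Pbx2		CLO, CLP, or CPO		21982646	Foxg1-Cre and Tcfap2a-Cre driven Pbx1;Pbx2 compound mutant mice.
T3-09	compound	Pbx1;Wnt9b		CLO or CLP	bilateral CL at 100%	21982646	Foxg1-Cre;Pbx1+/-;Wnt9b F/F mice show CP.
T3-10	compound	Pbx1;Pbx3		CLO, CLP, or CPO		21982646	Pbx1;Pbx3 compound mutant mice.
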