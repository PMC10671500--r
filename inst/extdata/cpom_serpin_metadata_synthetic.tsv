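# 26-serpin family table for Cydia pomonella: id, chromosome, signal peptide,
# phylogenetic group/subgroup, predicted P1/P1' and target class, expression
# subgroups. Sequences are NOT included here: serpin_fixture() generates
# synthetic stand-in sequences engineered to annotate with these P1/P1'
# residues and inhibitory calls (decoy_type marks the engineered defect of
# the non-inhibitory members).
id	species	length	chromosome	signal_peptide	gene_group	subgroup	p1	p1p	target_class	inhibitory	decoy_type	stage_group	tissue_group
CpSPN1	C_pomonella	391	5	1-18	A	A2	Y	L	C	yes	-	I	II
CpSPN2	C_pomonella	397	1	1-20	A	A1	M	C	E	yes	-	II	III
CpSPN3	C_pomonella	456	3	1-17	B	B	K	F	T	yes	-	I	III
CpSPN4	C_pomonella	416	2	1-17	C	C2	R	I	T	yes	-	II	III
CpSPN5	C_pomonella	395	23	1-15	C	C1	R	F	T	yes	-	IV	I
CpSPN6	C_pomonella	439	1	1-17	D	D	R	S	T	yes	-	II	III
CpSPN7	C_pomonella	373	2	1-15	C	C4	R	F	T	yes	-	IV	I
CpSPN8	C_pomonella	413	19	1-17	C	C2	A	N	E	yes	-	IV	I
CpSPN9	C_pomonella	382	2	1-17	C	C3	R	R	T	yes	-	I	III
CpSPN10	C_pomonella	518	3	1-16	E	E	-	-	-	no	degraded	II	III
CpSPN11	C_pomonella	436	3	NO	F	F	L	I	C	yes	-	II	III
CpSPN12	C_pomonella	570	3	1-18	G	G	L	S	C	yes	-	II	III
CpSPN13	C_pomonella	432	3	1-19	F	F	R	T	T	yes	-	IV	III
CpSPN14	C_pomonella	390	2	1-16	C	C3	V	E	E	yes	-	IV	III
CpSPN15	C_pomonella	371	22	NO	A	A1	I	C	C	yes	-	III	III
CpSPN16	C_pomonella	394	2	1-15	C	C1	R	I	T	yes	-	II	III
CpSPN17	C_pomonella	418	15	NO	A	A1	Y	Q	C	yes	-	III	II
CpSPN18	C_pomonella	348	15	NO	A	A1	L	C	C	yes	-	III	III
CpSPN19	C_pomonella	391	15	NO	A	A1	L	C	C	yes	-	III	III
CpSPN20	C_pomonella	366	1	NO	E	E	-	-	-	no	degraded	IV	I
CpSPN21	C_pomonella	383	15	NO	A	A1	R	C	T	yes	-	III	II
CpSPN22	C_pomonella	276	5	NO	A	A2	-	-	-	no	truncated	III	I
CpSPN23	C_pomonella	345	15	NO	A	A1	Y	Q	C	yes	-	III	II
CpSPN24	C_pomonella	465	22	NO	A	A1	M	P	E	yes	-	III	II
CpSPN25	C_pomonella	814	5	NO	A	A2	V	G	E	yes	-	III	I
CpSPN26	C_pomonella	1405	16	NO	E	E	-	-	-	no	long_tail	IV	I
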