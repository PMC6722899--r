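gene	kind	isoform	donor_pos	donor_exon	acceptor_pos	acceptor_exon
HaAPN1	linear	V1	5046	exon8	6260	exon12
HaAPN1	linear	V2	1188	exon2	4150	exon5
HaAPN1	linear	V3	5042	exon8	6368	exon12
HaAPN1	linear	V4	4178	exon5	5671	exon10
HaAPN1	linear	V5	3786	exon4	5595	exon10
HaAPN1	linear	V6	4860	exon7	6942	exon14
HaAPN1	linear	V7	4172	exon5	6372	exon12
HaAPN1	linear	V8	4486	exon6	6918	exon14
HaAPN1	linear	V9	4589	exon6	7080	exon14
HaAPN1	linear	V10	4589	exon6	7101	exon14
HaAPN1	linear	V11	4589	exon6	7134	exon14
HaAPN1	linear	V12	4543	exon6	7109	exon14
HaAPN1	linear	V13	4453	exon6	7043	exon14
HaAPN1	linear	V14	4508	exon6	7179	exon14
HaAPN1	linear	V15	4183	exon5	7028	exon14
HaAPN1	linear	V16	4383	exon6	7107	exon14
HaAPN1	linear	V17	4083	exon5	7107	exon14
HaAPN1	linear	V18	4083	exon5	7161	exon14
HaAPN1	linear	V19	875	exon2	7049	exon14
HaAPN1	linear	V20	863	exon2	7131	exon14
HaAPN1	circular	C1	6693	exon13	5382	exon9
HaAPN1	circular	C2	6722	exon12	5381	exon9
HaAPN1	circular	C3	6682	exon13	5187	exon8
HaAPN1	circular	C4	6715	exon13	5117	exon8
HaAPN1	circular	C5	6731	exon13	5093	exon8
HaAPN1	circular	C6	6698	exon13	5035	exon8
HaAPN1	circular	C7	6640	intron12	4896	exon7
HaAPN1	circular	C8	6852	exon14	5080	exon8
HaAPN1	circular	C9	6698	exon13	4811	exon7
HaAPN1	circular	C10	6526	exon12	4535	exon6
HaAPN1	circular	C11	6540	exon12	4470	exon6
HaAPN1	circular	C12	7132	exon14	5050	exon8
HaAPN1	circular	C13	6725	exon13	4483	exon6
HaAPN1	circular	C14	6933	exon14	4537	exon6
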