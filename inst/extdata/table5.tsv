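gene	kind	isoform	donor_pos	donor_exon	acceptor_pos	acceptor_exon
HaAPN3	linear	V1	117	exon1	4661	exon10
HaAPN3	linear	V2	728	exon2	6830	exon14
HaAPN3	linear	V3	248	exon1	6592	exon14
HaAPN3	linear	V4	248	exon1	6842	exon14
HaAPN3	linear	V5	241	exon1	6706	exon14
HaAPN3	linear	V7	208	exon1	6699	exon14
HaAPN3	linear	V8	208	exon1	6792	exon14
HaAPN3	linear	V9	210	exon1	6731	exon14
HaAPN3	linear	V10	210	exon1	6758	exon14
HaAPN3	linear	V11	194	exon1	6758	exon14
HaAPN3	linear	V12	233	exon1	6790	exon14
HaAPN3	linear	V13	244	exon1	6818	exon14
HaAPN3	linear	V14	190	exon1	6789	exon14
HaAPN3	circular	C1	6364	exon13	175	exon1
HaAPN3	circular	C2	6610	exon14	386	exon1
HaAPN3	circular	C3	6601	exon14	380	exon1
HaAPN3	circular	C4	6650	exon14	365	exon1
HaAPN3	circular	C5	6608	exon14	412	exon1
HaAPN3	circular	C6	6360	exon13	766	exon2
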