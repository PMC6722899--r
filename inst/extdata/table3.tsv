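gene	isoform	deletion_start	deletion_end	premature_stop	clones_scd
HaAPN4	Wild-type	-	-	-	78
HaAPN4	V1	412	2319	No	2
HaAPN6	Wild-type	-	-	-	76
HaAPN6	V1	720	2408	No	1
HaAPN6	V2	563	2422	No	1
HaAPN6	V3	345	2766	Yes	2
HaAPN9	Wild-type	-	-	-	74
HaAPN9	V1	732	2897	No	2
HaAPN9	V2	570	2649	Yes	1
HaAPN9	V3	306	1557	Yes	2
HaAPN9	V4	320	2843	Yes	1
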