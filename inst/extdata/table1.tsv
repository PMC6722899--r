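isoform	deletion_start	deletion_end	premature_stop	predicted_mw_kda	clones_scd	clones_an	clones_lf256
Wild-type	-	-	No	112.8	111	59	45
V1	1637	2295	Yes	62.5	1	2	0
V2	460	1125	No	87.1	3	0	1
V3	1633	2403	No	83.7	7	8	2
V4	1153	2028	No	80.1	2	2	0
V5	890	1952	Yes	33.5	6	0	0
V6	1530	2745	Yes	67.9	2	0	0
V7	1147	2407	Yes	43.9	1	0	1
V8	1324	2721	No	61	1	2	0
V9	1427	2883	Yes	58.3	2	0	1
V10	1427	2904	Yes	57.3	3	0	0
V11	1427	2937	Yes	56.1	2	0	0
V12	1364	2912	Yes	55.1	3	0	0
V13	1291	2846	Yes	54.9	1	0	0
V14	1346	2982	Yes	51.1	2	1	0
V15	1158	2831	No	41	1	3	0
V16	1221	2910	Yes	49.9	1	0	0
V17	1058	2910	Yes	50.7	5	1	0
V18	1058	2964	Yes	43.2	1	0	0
V19	147	2852	No	55.1	1	0	0
V20	135	2934	Yes	8.1	4	2	0
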