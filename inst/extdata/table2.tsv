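isoform	deletion_start	deletion_end	premature_stop	clones_scd
Wild-type	-	-	-	55
V1	117	2301	Yes	1
V2	624	2851	Yes	2
V3	248	2713	Yes	5
V4	248	2963	Yes	1
V5	241	2827	Yes	3
V6	179	2758	No	1
V7	208	2820	No	1
V8	208	2913	No	3
V9	210	2852	No	1
V10	210	2879	No	1
V11	194	2879	Yes	1
V12	233	2911	No	1
V13	244	2939	Yes	1
V14	190	2910	No	3
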