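marker_id	gene_id	fwd_end_tss_rel	rev_end_tss_rel	allele0	allele2	notes
PR_01	LalbFTa1	-8280	-7770	511	NA	monomorphic
PR_02	LalbFTa1	-7874	-7160	715	NA	monomorphic
PR_03	LalbFTa1	-7327	-6626	702	no_product	PAV
PR_04	LalbFTa1	-6980	-6109	872	no_product	PAV
PR_05a	LalbFTa1	-6203	-5430	774|no_product	850|2207	multi-allelic encoding a; 850 approximate
PR_05b	LalbFTa1	-6203	-5430	774|850|2207	no_product	multi-allelic encoding b; 850 approximate
PR_06	LalbFTa1	-5519	-4763	757	NA	monomorphic
PR_07	LalbFTa1	-4848	-4401	448	NA	monomorphic
PR_08	LalbFTa1	-4848	-4079	770	NA	monomorphic
PR_09	LalbFTa1	-4161	-3336	826	736	90 bp deletion; heterozygote callable
PR_10	LalbFTa1	-3526	-2733	794	NA	8 bp insertion unresolvable on standard agarose
PR_11	LalbFTa1	-2800	-2128	673	NA	monomorphic
PR_12	LalbFTa1	-2258	-1509	750	NA	monomorphic
PR_13	LalbFTa1	-1725	-1096	630	401	alternative product approximate; putative repetitive element
PR_14	LalbFTa1	-1241	-442	800	NA	monomorphic
PR_15	LalbFTa1	-511	229	741	NA	product interval crosses the TSS
QTL11	LalbFTa1	3390	1169	2218	1535	third intron; published length deviates from the inclusive span
PR_74	LalbFTa1	-6980	-6029	951	380	published length deviates from the inclusive span
PR_75	LalbFTa1	-6057	-5739	319	1523	heterozygote callable
PR_76	LalbFTa1	-5732	-5430	303	362	heterozygote callable
PR_16	LalbFTa2	-7866	-7163	704	676	heterozygote callable
PR_17	LalbFTa2	-7287	-6615	673	NA	monomorphic
PR_18a	LalbFTa2	-6826	-6120	707	950	het folded into allele-0 class
PR_18b	LalbFTa2	-6826	-6120	950	707	het folded into allele-0 class
PR_19a	LalbFTa2	-6214	-5515	700	927|no_product	het folded into allele-0 class
PR_19b	LalbFTa2	-6214	-5515	927|no_product	700	het folded into allele-0 class
PR_20	LalbFTa2	-5626	-4914	713	661	heterozygote callable
PR_21	LalbFTa2	-5014	-4345	700	NA	monomorphic; published length deviates from the inclusive span
PR_22	LalbFTa2	-4626	-3893	734	NA	monomorphic
PR_23	LalbFTa2	-3965	-3266	700	NA	monomorphic
PR_24	LalbFTa2	-3383	-2783	601	NA	monomorphic
PR_25	LalbFTa2	-2880	-2101	780	no_product	monomorphic in panel
PR_26	LalbFTa2	-2182	-1409	774	NA	monomorphic
PR_27	LalbFTa2	-1691	-1137	555	NA	monomorphic
PR_28	LalbFTa2	-1279	-428	852	NA	monomorphic
PR_29	LalbFTa2	-564	275	840	NA	monomorphic
PR_77a	LalbFTa2	-1279	-1137	157	143	longer secondary products possible
PR_77b	LalbFTa2	-1279	-1137	157	143	longer secondary products possible
PR_78	LalbFTa2	1335	1050	286	360	first intron
PR_79	LalbFTa2	2074	1854	249	271	published length deviates from the inclusive span
PR_30	LalbFTc1	-8065	-7254	812	no_product	PAV
PR_58a	LalbFTc1	-8065	-5562	2504	378	multi-allelic encoding a; heterozygote callable
PR_58b	LalbFTc1	-8065	-5562	2504|378	no_product|116	multi-allelic encoding b
PR_58c	LalbFTc1	-8065	-5562	2504|378|no_product	116	multi-allelic encoding c
PR_60a	LalbFTc1	-8065	-4899	no_product	1041|779	het folded into allele-2 class
PR_60b	LalbFTc1	-8065	-4899	no_product|1041	779	het folded into allele-2 class
PR_60c	LalbFTc1	-8065	-4899	no_product|1041	779	het folded into allele-0 class
PR_31	LalbFTc1	-7312	-6553	760	no_product	co-segregates with PR_30
PR_66	LalbFTc1	-7312	-4320	2993	no_product	PAV
PR_33	LalbFTc1	-6242	-5562	681	no_product	PAV
PR_34	LalbFTc1	-5694	-4899	796	no_product	PAV
PR_80	LalbFTc1	-5202	-4944	259	204	24 bp insertion plus adjacent 75 bp deletion
PR_35a	LalbFTc1	-4968	-4320	649|no_product	625	heterozygote callable
PR_35b	LalbFTc1	-4968	-4320	649	625|no_product	het folded into allele-2 class
PR_61	LalbFTc1	-4968	-3254	1715	no_product	PAV
PR_36a	LalbFTc1	-4585	-3860	726	482|no_product	het folded into allele-0 class
PR_36b	LalbFTc1	-4585	-3860	482	726|no_product	het folded into allele-0 class
PR_37	LalbFTc1	-3965	-3254	712	no_product	PAV
PR_38	LalbFTc1	-3403	-2695	709	no_product	PAV
PR_67	LalbFTc1	-3403	-451	2953	no_product	co-segregates with PR_39/PR_62/PR_70
PR_39	LalbFTc1	-2908	-2262	no_product	647	PAV
PR_62	LalbFTc1	-2908	-1179	1730|no_product	647	multi-allelic encoding
PR_40	LalbFTc1	-2365	-1591	775	no_product	rare unknown polymorphism
PR_41	LalbFTc1	-1944	-1179	no_product	766	PAV
PR_42a	LalbFTc1	-1259	-451	802|809	774|781	7 bp classes unresolvable within each allele
PR_42b	LalbFTc1	-1259	-451	NA	850	allele-0 class open-ended; 850 approximate
PR_71a	LalbFTc1	-970	-714	222|229|250	257	heterozygote callable
PR_71b	LalbFTc1	-970	-714	250|257	222|229	heterozygote callable
PR_71c	LalbFTc1	-970	-714	NA	280	allele-0 class open-ended; 280 approximate
PR_71d	LalbFTc1	-970	-714	250	NA	allele-2 class open-ended
PR_70	LalbFTc1	-875	-600	no_product	276	PAV
PR_43	LalbFTc1	-560	140	701	NA	monomorphic; targets no catalogued mutation
PR_44	LalbFTc2	-7711	-7066	646	NA	monomorphic
PR_45	LalbFTc2	-7161	-6557	605	NA	monomorphic
PR_46	LalbFTc2	-6635	-6022	614	NA	monomorphic
PR_47	LalbFTc2	-6109	-5353	757	NA	monomorphic
PR_48	LalbFTc2	-5413	-4692	722	NA	monomorphic
PR_49	LalbFTc2	-4787	-4340	448	NA	monomorphic
PR_50	LalbFTc2	-4454	-3722	733	NA	monomorphic
PR_51	LalbFTc2	-3822	-3088	735	NA	monomorphic
PR_52	LalbFTc2	-3180	-2641	540	NA	monomorphic
PR_53	LalbFTc2	-2745	-1984	762	NA	monomorphic
PR_54	LalbFTc2	-2087	-1331	757	NA	monomorphic
PR_55	LalbFTc2	-1418	-951	468	NA	monomorphic
PR_56	LalbFTc2	-1095	-252	844	NA	monomorphic
PR_57	LalbFTc2	-263	355	619	no_product	selective towards one winter cultivar
PR_64	LalbFTc2	1899	355	1588	no_product	second intron; published length deviates from the inclusive span
PR_73	LalbFTc2	2567	4624	2058|no_product	600	third intron
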