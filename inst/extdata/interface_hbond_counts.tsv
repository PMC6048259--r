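pair	tlv	tdelv	hbr1_printed	tl	tdel	hbr2_printed	flag_printed
D277-S279	13	37	2.85	0	0	0	Yes
D262-W489	28	57	2.04	48	18	0.37	Yes
E427-K266	28	56	2	56	61	1.09	Yes
H426-K266	10	20	2	0	0	0	Yes
E458-K255	17	33	1.94	32	37	1.16	Yes
R461-D262	94	108	1.15	145	93	0.64	Yes
D462-K255	47	52	1.11	53	75	1.42	No
R258-E458	160	170	1.06	240	216	0.9	Yes
D273-K325	66	69	1.05	97	106	1.09	No
R318-E249	116	118	1.02	246	224	0.91	Yes
K263-S493	33	33	1	38	61	1.61	No
E457-K263	79	74	0.937	124	116	0.935	Yes
K321-Y276	21	19	0.9	22	11	0.5	Yes
R454-M250	35	24	0.69	58	42	0.72	No
D277-K321	56	38	0.68	81	90	1.11	No
D277-K325	33	22	0.67	43	32	0.74	No
D273-K321	44	24	0.55	47	44	0.94	No
R454-E249	46	18	0.39	0	0	0	Yes
E457-K271	27	9	0.33	30	30	1	No
H494-T270	21	7	0.33	37	5	0.14	Yes
R461-F252	61	16	0.26	56	3	0.05	Yes
D425-K266	13	3	0.23	0	0	0	Yes
R611-E398	183	0	0	0	0	0	-
R377-D574	164	0	0	0	0	0	-
R454-E248	94	0	0	180	0	0	-
D390-H86	79	0	0	107	0	0	-
G617-H83	65	0	0	0	0	0	-
S88-T565	57	0	0	0	0	0	-
R491-D116	48	0	0	67	0	0	-
T384-T571	42	0	0	0	0	0	-
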