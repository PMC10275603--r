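site	total_reads	variant_reads
shared_1	147	84
shared_2	309	44
shared_3	73	40
shared_4	68	8
shared_5	170	27
shared_6	92	22
shared_7	129	18
shared_8	100	34
shared_9	73	35
shared_10	131	31
shared_11	56	6
shared_12	120	54
shared_13	92	3
shared_14	119	1
shared_15	85	11
shared_16	137	4
shared_17	180	95
shared_18	70	7
shared_19	32	17
shared_20	112	2
shared_21	31	7
shared_22	252	2
shared_23	148	16
shared_24	64	1
shared_25	115	4
shared_26	146	70
shared_27	70	1
shared_28	82	2
shared_29	70	11
shared_30	193	89
shared_31	103	3
shared_32	49	7
shared_33	137	73
shared_34	100	4
shared_35	230	7
shared_36	131	4
shared_37	148	17
shared_38	139	0
primary_1	103	10
primary_2	141	7
primary_3	101	8
primary_4	76	7
primary_5	154	1
primary_6	78	1
primary_7	143	1
primary_8	115	42
primary_9	96	45
primary_10	75	10
primary_11	108	6
primary_12	87	4
primary_13	50	0
primary_14	124	2
primary_15	129	1
primary_16	105	2
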