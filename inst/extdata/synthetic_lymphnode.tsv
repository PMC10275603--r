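site	total_reads	variant_reads
shared_1	53	23
shared_2	118	15
shared_3	183	76
shared_4	115	13
shared_5	77	10
shared_6	85	20
shared_7	142	26
shared_8	171	84
shared_9	97	23
shared_10	140	35
shared_11	52	4
shared_12	111	51
shared_13	68	0
shared_14	98	3
shared_15	104	11
shared_16	109	0
shared_17	191	89
shared_18	65	1
shared_19	114	53
shared_20	68	1
shared_21	56	9
shared_22	79	1
shared_23	94	10
shared_24	45	2
shared_25	76	2
shared_26	95	45
shared_27	47	1
shared_28	92	6
shared_29	126	14
shared_30	89	53
shared_31	68	3
shared_32	68	9
shared_33	177	79
shared_34	49	0
shared_35	104	1
shared_36	84	5
shared_37	61	8
shared_38	141	3
met_1	108	10
met_2	99	11
met_3	112	29
met_4	146	33
met_5	118	13
met_6	38	2
met_7	173	11
met_8	91	3
met_9	79	20
met_10	70	25
met_11	28	4
met_12	93	20
met_13	92	17
met_14	172	62
met_15	133	51
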