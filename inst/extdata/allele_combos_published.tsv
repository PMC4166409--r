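combo	n	min	max	mean	sd
CTTATTGA	3	1.63	2.23	1.88	0.31
TGTATTGA	7	1.46	2.58	2.17	0.37
CGTAGTGA	2	2.18	2.34	2.26	0.11
CTTATTGC	6	1.96	2.86	2.29	0.33
TTTATTGA	11	1.95	3.25	2.32	0.40
CGCATTGA	9	2.08	2.83	2.38	0.26
CTCGTTAA	1	2.4	2.4	2.40	NA
CTTATTAA	2	2.16	2.66	2.41	0.35
CTCATTGA	26	1.8	3.01	2.41	0.33
CTTGTTGC	2	2.16	2.69	2.43	0.37
CTCATTGC	9	2.11	3.03	2.44	0.33
CGTATTGA	5	2.31	2.57	2.47	0.13
CTTATCGC	2	2.42	2.52	2.47	0.07
CGTATTGC	1	2.5	2.5	2.50	NA
TTCGTTAC	1	3.56	3.56	3.56	NA
TTCAGTAC	1	3.58	3.58	3.58	NA
TGCAGCGC	1	3.68	3.68	3.68	NA
TGCGTTGC	1	3.7	3.7	3.70	NA
TGCGTTAA	1	3.72	3.72	3.72	NA
TGCGTTAC	1	3.79	3.79	3.79	NA
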