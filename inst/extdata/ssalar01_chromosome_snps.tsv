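chromosome	linkage_group	n_snps
1	17	3411
2	1	774
3	11	2007
4	28	2189
5	12	1496
6	4	657
7	24	633
8	19	634
9	10	2266
10	2	2015
11	9	1641
12	6	1804
13	5	1942
14	3	1576
15	8	1830
16	23	1398
17	22	1085
18	16	1443
19	13	1247
20	25	1381
21	14	950
22	32	652
23	18	589
24	7	2134
25	20	950
26	21	927
27	15	980
28	33	807
29	31	796
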