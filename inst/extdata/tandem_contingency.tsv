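# Published head-to-head tandem-NLR contingency counts for nine grass
# species, transcribed from the printed analysis tables. Two panels:
# grouping by NLR-ID status (panel=id) and by membership of the major
# integration clade MIC1 (panel=mic1). Cells: a = group & tandem member,
# b = group & single, c = other & tandem member, d = other & single
# (gene-level, deduplicated). printed_p is the printed two-sided Fisher
# exact p-value. Note: per-species cells in the mic1 panel sum to 51/267
# for a/c against the printed pooled 52/266 (footnoted special tandems
# are counted at the pooled level only); pooled rows are transcribed
# as printed.
panel	species	n_tandems	a	b	c	d	printed_p
id	A. tauschii	13	10	73	16	639	2.24e-04
id	B. distachyon	22	5	14	39	314	6.01e-02
id	H. vulgare	10	3	24	17	418	1.04e-01
id	O. sativa	25	4	15	46	453	1.00e-01
id	S. bicolor	15	5	19	25	292	4.79e-02
id	S. italica	11	1	11	21	405	4.66e-01
id	T. aestivum	48	17	159	79	2341	1.70e-04
id	T. urartu	13	5	38	21	494	4.17e-02
id	Z. mays	2	0	12	4	155	1.00e+00
id	All	159	50	365	268	5511	1.02e-08
mic1	A. tauschii	13	4	43	22	669	7.66e-02
mic1	B. distachyon	22	8	17	36	311	4.69e-03
mic1	H. vulgare	10	4	32	16	410	6.11e-02
mic1	O. sativa	25	5	12	45	456	1.74e-02
mic1	S. bicolor	15	2	17	28	294	6.78e-01
mic1	S. italica	11	5	8	17	408	1.98e-04
mic1	T. aestivum	48	17	149	79	2351	8.13e-05
mic1	T. urartu	13	6	32	20	500	5.60e-03
mic1	Z. mays	2	0	1	4	166	1.00e+00
mic1	All	159	52	310	266	5566	4.12e-12
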