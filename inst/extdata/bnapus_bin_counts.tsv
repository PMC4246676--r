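# Per-functional-category (MapMan BIN) counts of gene-level "S" and "T" calls
# in the two-accession oilseed rape embryo comparison.
bin_code	n_S	n_T	bin_name
35	197	232	not assigned
29	114	142	protein
27	77	91	RNA
26	31	37	misc
34	30	37	transport
20	31	35	stress
30	27	37	signalling
31	30	25	cell
28	31	19	DNA
1	9	29	photosynthesis
33	16	22	development
11	15	18	lipid metabolism
13	13	19	amino acid metabolism
10	22	7	cell wall
16	10	19	secondary metabolism
17	12	10	hormone metabolism
23	9	9	nucleotide metabolism
9	1	15	mitochondrial electron transport / ATP synthesis
3	7	7	minor CHO metabolism
21	4	10	redox
8	5	7	TCA / org transformation
4	4	5	glycolysis
2	4	1	major CHO metabolism
18	3	2	co-factor and vitamin metabolism
19	3	2	tetrapyrrole synthesis
7	3	1	oxidative pentose phosphate pathway
5	1	2	fermentation
12	2	1	N-metabolism
15	1	2	metal handling
14	1	1	S-assimilation
24	1	1	biodegradation of xenobiotics
32	0	2	micro RNA
6	1	0	gluconeogenesis / glyoxylate cycle
22	1	0	polyamine metabolism
25	1	0	C1-metabolism
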