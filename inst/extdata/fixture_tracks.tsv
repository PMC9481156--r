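frame	cell_id	parent_id	fate	area	g1
0	1	-1	NB	1.1	0.1
0	2	-1	NB	1.2	0.2
0	3	-1	DEL	1.3	0.3
0	4	-1	NB	1.4	0.4
0	5	-1	NB	1.5	0.5
0	6	-1	NB	1.6	0.6
0	7	-1	NB	1.7	0.7
0	8	-1	NB	1.8	0.8
1	1	-1	NB	1.1	0.1
1	2	-1	DIV	1.2	0.2
1	4	-1	NB	1.4	0.4
1	5	-1	NB	1.5	0.5
1	6	-1	NB	1.6	0.6
1	7	-1	NB	1.7	0.7
1	8	-1	NB	1.8	0.8
2	1	-1	NB	1.1	0.1
2	4	-1	NB	1.4	0.4
2	5	-1	NB	1.5	0.5
2	6	-1	NB	1.6	0.6
2	7	-1	NB	1.7	0.7
2	8	-1	NB	1.8	0.8
2	9	2	NB	1.9	0.9
2	10	2	NB	2	1
3	1	-1	CENSOR	1.1	0.1
3	4	-1	CENSOR	1.4	0.4
3	5	-1	CENSOR	1.5	0.5
3	6	-1	CENSOR	1.6	0.6
3	7	-1	CENSOR	1.7	0.7
3	8	-1	CENSOR	1.8	0.8
3	9	-1	CENSOR	1.9	0.9
3	10	-1	CENSOR	2	1
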