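frame	cell_id_a	cell_id_b
0	1	2
0	2	3
0	3	4
0	4	5
0	5	6
0	6	7
0	7	8
0	8	1
1	1	2
1	2	4
1	4	5
1	5	6
1	6	7
1	7	8
1	8	1
2	1	9
2	9	10
2	10	4
2	4	5
2	5	6
2	6	7
2	7	8
2	8	1
3	1	9
3	9	10
3	10	4
3	4	5
3	5	6
3	6	7
3	7	8
3	8	1
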