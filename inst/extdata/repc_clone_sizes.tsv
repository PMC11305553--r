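size	n_clones
1	4907
2	809
3	282
4	133
5	74
6	46
7	31
8	22
9	16
10	12
11	9
12	7
13	6
14	5
15	4
16	3
17	3
18	2
19	2
20	2
21	1
22	1
23	1
24	1
25	1
26	1
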