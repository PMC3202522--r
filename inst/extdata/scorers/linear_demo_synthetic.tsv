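position	A	C	G	U
0	52.0	0	0	0
1	-1.0	1.5	2.0	-1.5
2	0.5	0.0	0.5	0.5
3	1.0	-0.5	-0.5	0.5
4	0.5	0.0	0.0	0.5
5	0.0	0.0	0.5	0.0
6	0.5	-0.5	0.0	0.5
7	0.0	0.0	0.0	0.5
8	0.5	0.0	-0.5	0.5
9	0.5	0.0	0.0	0.5
10	0.5	-0.5	-0.5	1.0
11	0.5	0.0	0.0	0.5
12	0.5	-0.5	0.0	0.5
13	1.0	-1.0	-2.0	1.0
14	1.0	-0.5	-0.5	1.0
15	1.5	-1.0	-1.0	1.5
16	1.5	-1.0	-1.0	1.5
17	1.5	-1.0	-1.0	1.5
18	1.5	-1.5	-1.5	1.5
19	2.5	-2.5	-2.5	2.0
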