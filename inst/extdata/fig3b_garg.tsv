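#garg	1
#L	10
#NODES
#id	is_sample	time	metadata
1	1	0	a
2	1	0	b
3	1	0	c
4	0	1	d
5	0	1	e
6	0	2	f
7	0	2.5	g
8	0	3	h
9	0	4.5	i
10	0	8	j
11	0	5	k
12	0	1	l
13	0	4	m
14	0	3.5	n
15	0	7	o
16	0	6	p
17	0	9	q
#EDGES
#child	parent	left	right
1	4	0	10
2	12	0	10
3	5	0	10
4	6	2	10
4	7	0	2
5	6	0	7
5	8	7	10
6	14	0	10
7	8	0	5
7	10	5	10
8	13	0	10
9	16	0	10
10	17	0	10
11	16	0	10
12	9	3	10
12	13	0	3
13	11	0	10
14	9	8	10
14	11	0	8
15	10	6	10
15	17	0	6
16	15	0	10
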