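#earg	1
#L	10
#EVENTS
#id	kind	breakpoint	time	metadata
1	sample		0	a
2	sample		0	b
3	sample		0	c
4	recombination	2	1	d
5	recombination	7	1	e
6	common-ancestor		2	f
7	recombination	5	2.5	g
8	common-ancestor		3	h
9	common-ancestor		4.5	i
10	common-ancestor		8	j
11	common-ancestor		5	k
12	recombination	3	1	l
13	common-ancestor		4	m
14	recombination	8	3.5	n
15	recombination	6	7	o
16	common-ancestor		6	p
17	common-ancestor		9	q
#EDGES
#child	parent	side
1	4	only
2	12	only
3	5	only
4	7	left
4	6	right
5	6	left
5	8	right
6	14	only
7	8	left
7	10	right
8	13	only
9	16	only
10	17	only
11	16	only
12	13	left
12	9	right
13	11	only
14	11	left
14	9	right
15	17	left
15	10	right
16	15	only
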