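chrY	18450000	18480000	P8a
chrY	18485000	18515000	P8b
chrY	18600000	18630000	P7a
chrY	18635000	18665000	P7b
chrY	18800000	18830000	P6a
chrY	18840000	18870000	P6b
chrY	19100000	19130000	P5a
chrY	19140000	19170000	P5b
chrY	19500000	19530000	P4a
chrY	19545000	19575000	P4b
chrY	23000000	23020000	b1
chrY	23030000	23060000	t1
chrY	23070000	23100000	t2
chrY	23110000	23130000	b2
chrY	23140000	23160000	g1
chrY	23170000	23190000	r1
chrY	23200000	23220000	r2
chrY	23230000	23290000	Gr1
chrY	23300000	23320000	b3
chrY	23330000	23360000	y1
chrY	23370000	23390000	g2
chrY	23400000	23420000	r3
chrY	23430000	23450000	r4
chrY	23460000	23490000	y2
chrY	23500000	23520000	g3
chrY	23530000	23550000	b4
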