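char_id	locus	position	kind	A	B	C	D	E	F	G	H
c1	ycf6-psbM	159	substitution	T	T	T	T	T	G	T	T
c2	ycf6-psbM	326	indel	-	-	-	TATAT	-	-	-	TATAT
c3	trnT-trnL	9	indel	-	TAGAACCG	-	-	-	-	TAGAACCG	-
c4	trnT-trnL	60	indel	-	-	-	-	-	-	TATTTG	-
c5	rps16	304	indel	-	-	TGTCATG	-	-	-	-	-
c6	rps16	368	substitution	G	G	A	G	G	G	G	G
c7	atpI-atpH	300	substitution	T	T	T	T	T	T	T	G
c8	atpI-atpH	342	substitution	A	A	A	C	C	A	A	C
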