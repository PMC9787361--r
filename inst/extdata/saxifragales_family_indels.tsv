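family	total	trnA	trnI	trnK	trnL	trnV	atpF	clpPa	clpPb	ndhA	ndhB	petB	petD	rpl16	rpl2	rpoC1	rps12	rps16	ycf3a	ycf3b
Altingiaceae	10/4/14	-	1/-/1	2/1/3	-	-/1/1	2/-/2	-	-	-	-	-	1/-/1	1/-/1	-	1/-/1	-	1/-/1	-/1/1	1/1/2
Cercidiphyllaceae	2/3/5	-	-	-	-	-	-	-/1/1	-	1/-/1	-	-	-/1/1	-	-	1/-/1	-	-/1/1	-	-
Crassulaceae	26/15/41	-	1/-/1	2/1/3	1/1/2	-/1/1	-	2/2/4	5/-/5	3/1/4	-	1/1/2	0/2/2	1/1/2	1/-/1	-/1/1	-	5/1/6	2/2/4	2/1/3
Daphniphyllaceae	1/2/3	-	-	-/1/1	-	-	-	-	-/1/1	-	-	1/-/1	-	-	-	-	-	-	-	-
Grossulariaceae	6/6/12	-	1/-/1	-	-	1/-/1	-/1/1	-	-	-/1/1	-	-	3/-/3	1/2/3	-	-	-/1/1	-	-	-/1/1
Haloragaceae	5/11/16	-/1/1	-	1/-/1	-	-	-/2/2	1/-/1	-	2/3/5	-	-	-	-	-	-/2/2	-	-/1/1	1/1/2	-/1/1
Hamamelidaceae	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Iteaceae	2/8/10	-	-	-/2/2	-	-	-	-	-	-/1/1	-/1/1	-	-	1/1/2	-	-/1/1	-	-/2/2	-	1/-/1
Paeoniaceae	43/39/82	1/-/1	3/2/5	3/4/7	-	2/2/4	2/6/8	4/3/7	2/3/5	5/1/6	-	-	5/4/9	3/4/7	-/1/1	2/3/5	-	6/4/10	3/1/4	2/1/3
Penthoraceae	2/5/7	-	1/-/1	-/1/1	-	1/-/1	-/1/1	-/1/1	-	-/1/1	-	-/1/1	-	-	-	-	-	-	-	-
Saxifragaceae	4/2/6	-	-	-	-	-	-	-	3/-/3	-	-	-/2/2	1/-/1	-	-	-	-	-	-	-
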