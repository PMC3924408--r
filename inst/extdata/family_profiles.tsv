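name	size	length_min	length_max	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
SAK	69	120	150	7.1416	0	4.7265	5.8172	5.9384	6.1202	1.965	5.116	11.946	8.3535	2.0862	6.9771	4.0945	3.402	4.787	5.7479	4.6312	5.9384	0.0866	5.1247
SK	167	380	440	7.332	0	4.8525	9.5272	3.4305	8.9495	2.0174	5.2524	10.487	8.5763	2.1418	3.6082	4.2037	3.4927	4.9147	5.9012	4.7547	6.0967	0.0889	4.3726
tPA	11	500	560	9.6236	3.7468	4.6707	5.7485	3.302	6.0479	1.9418	5.0556	8.3832	8.2549	2.0616	3.4731	4.0462	3.3618	7.2968	5.6801	4.5766	5.8683	2.6518	4.2087
UK	109	390	430	7.0694	3.7532	4.6787	5.7584	3.3076	8.629	1.9452	5.0643	8.3976	8.2691	2.0651	3.479	4.0531	3.3676	4.7386	8.2605	4.5844	5.8783	2.485	4.2159
NEG	501	100	600	8.2583	1.3814	5.4655	6.7267	3.8639	7.0771	2.2723	5.9159	5.8058	9.6597	2.4124	4.0641	4.7347	3.9339	5.5355	6.6466	5.3554	6.8669	1.1011	2.9229
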