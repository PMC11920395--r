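variant_type	frequency	afr	amr	sas	eas	asj	nfe	fin
missense	common	141538	105985	103281	93436	81093	79200	70438
ptv	common	6694	5451	5306	5321	4781	4447	4263
synonymous	common	115737	84509	78068	66795	60801	59348	50748
missense	rare	652095	949110	1038844	619444	103944	2384930	212055
ptv	rare	49241	74192	79637	48861	11469	219425	22077
synonymous	rare	345648	491853	536568	317486	50053	1143528	99547
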