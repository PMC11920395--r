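variant_type	frequency	afr	sas	eas	asj	nfe_20k	nfe_43k	nfe_440k
missense	common	150816	112862	99032	88248	78198	78736	78272
ptv	common	7647	6278	5718	5474	4650	4630	4684
synonymous	common	125683	84416	72860	65668	59161	59429	59271
missense	rare	859599	854077	288419	58609	1175279	1859809	6023520
ptv	rare	69882	70874	22267	6639	112946	189338	772007
synonymous	rare	456784	445392	155012	29249	576402	886465	2633791
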