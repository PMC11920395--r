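variant_type	max_diverse_43k	nfe_43k	nfe_440k	full_460k
missense	2919200	1938545	6101792	7218601
ptv	265806	193968	776691	890755
synonymous	1492034	945894	2693062	3243081
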