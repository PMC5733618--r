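group	n	n_affected_or_concordant
families	9	NA
total	315	74
male	169	43
female	146	31
parent_offspring	443	65
sib_sib	317	73
sister_sister	101	12
brother_brother	74	32
sister_brother	142	32
grandparental	340	13
avuncular	840	38
cousin	811	54
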