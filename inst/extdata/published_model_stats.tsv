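stage	model_id	neg2lnL	n_estimated	printed_p	printed_AIC
association	sporadic_no_assoc	339.65	1	NA	341.65
association	sporadic_equal_assoc	284.88	2	<0.001	288.88
association	sporadic_parent_assoc	284.24	3	<0.001	290.24
association	sporadic_free_assoc	284.12	4	<0.001	292.12
transmission	sporadic_equal_assoc	284.88	2	<0.001	288.88
transmission	general	193.50	8	NA	203.50
transmission	homogeneous_general	193.78	7	0.60	207.78
transmission	environmental	204.44	5	0.012	214.44
transmission	tau_ab_free	196.39	6	0.24	206.39
transmission	codominant	253.86	5	<0.001	263.86
transmission	dominant	253.88	4	<0.001	261.88
transmission	recessive	253.97	4	<0.001	261.97
transmission	additive	263.04	4	<0.001	271.04
transmission	decreasing	253.89	5	<0.001	263.89
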