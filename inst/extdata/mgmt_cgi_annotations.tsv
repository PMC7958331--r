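annotation	local_start	local_end	gc_percent	obs_exp_cpg
P1-CGI	1	2019	63	0.63
US-CGI	241	720	65.2	1.1
DS-CGI	901	1440	73.1	0.79
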