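threshold	raw_overlap	eff_overlap	eff_discovery_sig	eff_target_sig	eff_target_total	expected_prop	observed_prop	p_binomial_published
0.01	17	15	386	450	17046	0.026	0.039	8.259e-02
0.05	196	171	1430	1467	17046	0.086	0.120	9.83e-06
0.1	493	420	2433	2579	17046	0.151	0.173	1.85e-03
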