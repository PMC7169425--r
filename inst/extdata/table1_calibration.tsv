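panel	window_het	cutoff_mb	intercept	slope	r2	flag
18198	0	1	0.011	0.81	0.762	
18198	1	1	0.011	0.853	0.76	
21615	0	1	0.008	0.701	0.76	
21615	1	1	0.011	0.859	0.78	
25511	0	1	0.008	0.692	0.784	
25511	1	1	0.012	0.887	0.78	
18198	0	2	0.008	0.77	0.75	
18198	1	2	0.012	0.82	0.75	
21615	0	2	0.004	0.587	0.73	
21615	1	2	0.008	0.83	0.77	
25511	0	2	0.004	0.481	0.735	
25511	1	2	0.009	0.829	0.77	
18198	0	4	0.004	0.695	0.71	
18198	1	4	0.08	0.743	0.72	as_printed_probable_typo
21615	0	4	0.001	0.35	0.6	
21615	1	4	0.003	0.74	0.73	
25511	0	4	0.004	0.187	0.472	
25511	1	4	0.005	0.664	0.714	
18198	0	10	0.0009	0.388	0.52	
18198	1	10	0.004	0.48	0.55	
21615	0	10	0.01	0.02	0.35	
21615	1	10	0.002	0.427	0.42	
25511	0	10	0.019	0.001	0.01	
25511	1	10	0.01	0.25	0.424	
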