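group	intercept	intercept_se	slope	slope_se	dry_fresh_factor	dry_fresh_se
poduromorpha	0.50	0.06	2.22	0.10	3.33	0.20
poduromorpha	0.58	0.08	2.30	0.12	3.33	0.20
entomobryomorpha	0.65	0.05	2.48	0.09	3.30	0.18
entomobryomorpha	0.60	0.07	2.40	0.11	3.30	0.18
symphypleona	0.72	0.06	2.55	0.10	3.40	0.22
neelipleona	0.45	0.09	2.20	0.14	3.25	0.25
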