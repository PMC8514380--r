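sample_id	tp53_signature_score	status_by_score	status_by_microarray
BR047	0.1707	Wild	Wild
BR038	0.3383	Wild	Wild
BR019	0.4267	Wild	Wild
BR044	0.5178	Wild	Wild
BR033	0.5206	Wild	Wild
BR050	0.5406	Wild	Wild
BR034	0.5696	Wild	Wild
BR045	0.5910	Wild	Wild
BR063	0.6151	Wild	Wild
BR016	0.7157	Wild	Wild
BR024	0.7668	Wild	Wild
BR052	0.7820	Wild	Wild
BR036	0.8019	Wild	Wild
BR027	0.8796	Wild	Wild
BR048	0.9536	Wild	Wild
BR043	1.0681	Wild	Wild
BR058	1.1003	Wild	Wild
BR064	1.2907	Mutant	Mutant
BR040	1.4288	Mutant	Mutant
BR013	1.4350	Mutant	Wild
BR020	1.4504	Mutant	Mutant
BR035	1.4809	Mutant	Mutant
BR026	1.6511	Mutant	Mutant
BR046	1.6968	Mutant	Mutant
BR017	1.7842	Mutant	Mutant
BR010	1.9654	Mutant	Mutant
BR001	2.1603	Mutant	Mutant
BR005	2.1959	Mutant	Mutant
BR021	2.3457	Mutant	Mutant
BR022	2.3744	Mutant	Mutant
BR053	2.4841	Mutant	Mutant
BR011	2.5209	Mutant	Mutant
BR041	3.6260	Mutant	Mutant
BR009	4.0595	Mutant	Mutant
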