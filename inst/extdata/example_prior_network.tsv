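regulator	target	sign	weight
R001	G00006	unknown	1
R001	G00007	represses	1
R001	G00009	represses	1
R001	G00023	activates	1
R002	G00006	unknown	1
R002	G00009	activates	1
R002	G00034	represses	1
R002	G00039	activates	1
R002	G00042	activates	1
R002	G00045	activates	1
R003	G00010	represses	1
R003	G00013	activates	1
R003	G00019	activates	1
R003	G00021	activates	1
R003	G00026	represses	1
R003	G00035	activates	1
R003	G00048	activates	1
R003	G00050	represses	1
R004	G00011	represses	1
R004	G00025	activates	1
R004	G00026	activates	1
R004	G00028	activates	1
R004	G00035	activates	1
R004	G00042	represses	1
R004	G00046	represses	1
R005	G00013	activates	1
R005	G00016	activates	1
R005	G00019	activates	1
R005	G00032	represses	1
R005	G00043	activates	1
R005	G00046	activates	1
R006	G00004	activates	1
R006	G00014	activates	1
R006	G00028	activates	1
R006	G00035	activates	1
R006	G00036	represses	1
R006	G00044	unknown	1
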