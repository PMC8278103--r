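# Published SDAF vs mid-parent-heterosis Pearson correlation tests from a
# tropical hybrid rice field study: r and its 95% CI half-width, the t
# statistic, and degrees of freedom, overall and within female families.
trait	group	r	ci_halfwidth	t	df
height	overall	-0.330	0.062	-9.791	783
height	10A	-0.041	0.157	-0.512	154
height	2A	0.007	0.176	0.077	122
height	4A	0.031	0.145	0.419	181
height	6A	-0.044	0.227	-0.381	73
height	7A	-0.073	0.237	-0.592	66
height	A07	0.084	0.146	1.118	177
tillers	overall	0.299	0.064	8.725	778
tillers	10A	-0.143	0.155	-1.786	152
tillers	2A	0.058	0.176	0.644	121
tillers	4A	0.027	0.145	0.357	180
tillers	6A	0.032	0.227	0.269	73
tillers	7A	-0.084	0.239	-0.677	65
tillers	A07	0.045	0.146	0.601	177
panicle_length	overall	-0.430	0.057	-13.309	783
panicle_length	10A	-0.042	0.157	-0.516	154
panicle_length	2A	-0.084	0.175	-0.935	122
panicle_length	4A	0.081	0.144	1.094	181
panicle_length	6A	0.066	0.226	0.568	73
panicle_length	7A	0.013	0.238	0.103	66
panicle_length	A07	0.058	0.146	0.772	177
spikelets_filled	overall	-0.015	0.081	-0.363	588
spikelets_filled	10A	0.127	0.156	1.578	151
spikelets_filled	2A	0.063	0.177	0.687	120
spikelets_filled	4A	0.103	0.146	1.364	174
spikelets_filled	6A	0.027	0.228	0.230	72
spikelets_filled	7A	0.083	0.242	0.663	63
yield	overall	-0.131	0.069	-3.698	781
yield	10A	0.014	0.157	0.169	154
yield	2A	0.041	0.176	0.450	122
yield	4A	0.116	0.144	1.562	180
yield	6A	0.040	0.227	0.346	73
yield	7A	-0.022	0.238	-0.176	66
yield	A07	0.104	0.146	1.389	176
potential_yield	overall	-0.092	0.080	-2.225	585
potential_yield	10A	-0.031	0.159	-0.386	151
potential_yield	2A	-0.005	0.178	-0.059	120
potential_yield	4A	0.087	0.148	1.141	171
potential_yield	6A	0.042	0.228	0.360	72
potential_yield	7A	-0.008	0.244	-0.060	63
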