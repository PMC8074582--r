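label	nodes	clustering	density	assortativity
badtattoos	703.36	0.0071	0.0018	-0.0506
gonewildcurvy	1191.54	0.0064	0.0015	-0.1482
southpark	2031.81	0.0109	0.0008	-0.0236
HogwartsRP	54.09	0.3462	0.1432	-0.2259
redditblack	201.72	0.3055	0.0453	-0.1748
geology	554.54	0.0214	0.0025	-0.0541
hardwareswap	1712.27	0.0613	0.0025	-0.0818
counterstrike	446.81	0.0086	0.0025	-0.0668
stopsmoking	830.63	0.0503	0.0024	-0.1102
memes	443.27	0.0142	0.0023	-0.0313
feminism	675.36	0.0259	0.0022	-0.0310
introvert	581.90	0.0145	0.0022	-0.0863
pizza	615.54	0.0198	0.0021	-0.0882
vegetarian	804.27	0.0266	0.0021	-0.0594
depression	2973.09	0.0139	0.0005	-0.0726
CrazyIdeas	2600.63	0.0127	0.0005	-0.0488
lifehacks	3126	0.0119	0.0004	-0.0635
conservatives	126.18	0.2698	0.0191	-0.4898
90daysgoal	169.27	0.4219	0.0545	-0.4184
csshelp	253.54	0.0526	0.0067	-0.4451
freedonuts	605.27	0.0228	0.0026	-0.3823
altgonewild	112.72	0.0075	0.0111	-0.3164
bonsai	318.45	0.3263	0.0128	-0.3188
colorado	464.90	0.0289	0.0036	0.04103
GreenBayPackers	1576.18	0.0317	0.0019	0.0159
beertrade	806.72	0.0413	0.0034	0.0100
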