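subject_id	group	phase_mean	phase_sd
1	healthy	6.272	0.019
2	healthy	6.265	0.016
3	healthy	6.279	0.025
4	healthy	6.275	0.022
5	healthy	6.276	0.016
6	healthy	6.275	0.016
7	healthy	6.277	0.018
8	healthy	6.278	0.019
9	stroke	6.273	0.017
10	stroke	6.255	0.016
11	stroke	6.263	0.016
12	stroke	6.255	0.015
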