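grouping	N	H_T	H_S	D_ST	G_ST	Nm
Total	312	0.3842	0.3136	0.0706	0.1838	2.22
Landraces	144	0.3672	0.3232	0.0440	0.1198	3.67
Modern	168	0.3652	0.3041	0.0611	0.1673	2.49
SP1-SP2	102	0.3594	0.3282	0.0312	0.0868	5.26
SP1-SP3	85	0.3363	0.3003	0.0360	0.1070	4.17
SP1-SP4	125	0.3452	0.2934	0.0518	0.1501	2.83
SP1-SP5	67	0.3307	0.2762	0.0545	0.1648	2.53
SP1-SP6	105	0.3690	0.3174	0.0516	0.1398	3.08
SP2-SP3	101	0.3737	0.3411	0.0326	0.0872	5.23
SP2-SP4	141	0.3521	0.3343	0.0178	0.0506	9.39
SP2-SP5	83	0.3628	0.3171	0.0457	0.1260	3.47
SP2-SP6	121	0.3844	0.3583	0.0261	0.0679	6.86
SP3-SP4	124	0.3549	0.3064	0.0485	0.1367	3.16
SP3-SP5	66	0.3445	0.2892	0.0553	0.1605	2.61
SP3-SP6	104	0.3304	0.2892	0.0412	0.1247	3.51
SP4-SP5	106	0.3176	0.2823	0.0353	0.1111	4.00
SP4-SP6	144	0.3658	0.3236	0.0422	0.1154	3.83
SP5-SP6	86	0.3594	0.3063	0.0531	0.1477	2.88
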