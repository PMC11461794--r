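tissue	participant	duplex_bases	n_snv	n_mnv	n_indel	n_sv
blood	1	1354242708	137	1	8	0
blood	2	1353042031	175	2	17	0
blood	3	1200540488	114	0	9	1
blood	4	1336908675	182	2	6	0
blood	5	1341009611	188	5	11	1
blood	6	1310508887	154	0	9	1
sperm	1	1129894519	32	0	107	13
sperm	2	1302208129	32	1	69	4
sperm	3	1214503210	29	0	67	15
sperm	4	1301231218	33	2	105	7
sperm	5	1236182547	31	0	92	10
sperm	6	1280782498	27	0	98	19
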