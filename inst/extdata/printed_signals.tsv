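drug	event	DE	D	ror	ci_low	prr	chi2
denosumab	death	16013	117857	3.478	3.42	3.142	23699.174
denosumab	osteonecrosis of jaw	6043	117857	53.025	51.377	50.358	193469.11
denosumab	back pain	2793	117857	2.432	2.342	2.398	2244.037
denosumab	tooth disorder	1929	117857	16.18	15.414	15.931	23239.1
denosumab	bone pain	1878	117857	6.523	6.223	6.435	8106.468
denosumab	hypocalcaemia	1805	117857	23.173	22.009	22.834	30578.129
denosumab	spinal fracture	1369	117857	15.963	15.073	15.79	16337.329
denosumab	pain in jaw	1314	117857	9.335	8.819	9.242	8831.068
denosumab	fracture	894	117857	6.768	6.323	6.725	4076.903
denosumab	tooth extraction	815	117857	11.487	10.681	11.415	6932.845
zoledronic acid	osteonecrosis	6980	36878	104.866	101.892	85.207	458676.62
zoledronic acid	death	5283	36878	3.645	3.539	3.266	8597.053
zoledronic acid	pain	4177	36878	3.963	3.836	3.627	8110.249
zoledronic acid	osteonecrosis of jaw	3696	36878	91.744	88.342	82.649	236587.42
zoledronic acid	tooth extraction	2321	36878	142.143	135.258	133.26	214317.12
zoledronic acid	bone disorder	2129	36878	68.221	65.038	64.34	110354.49
zoledronic acid	pyrexia	1957	36878	3.932	3.756	3.777	4002.168
zoledronic acid	arthralgia	1895	36878	3.364	3.211	3.242	2953.963
zoledronic acid	pain in jaw	1792	36878	44.097	41.93	42.002	63354.395
zoledronic acid	fall	1543	36878	3.039	2.887	2.953	2001.728
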