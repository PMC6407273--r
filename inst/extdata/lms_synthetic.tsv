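sex	age	M	S	L
male	18	81.4997463637512	0.0643	1
male	19	81.4179695371177	0.06465	1
male	20	81.336087280779	0.065	1
male	21	81.254099390718	0.06535	1
male	22	81.1720056623905	0.0657	1
male	23	81.0898058907242	0.06605	1
male	24	81.0074998701163	0.0664	1
male	25	80.9250873944325	0.06675	1
male	26	80.8425682570046	0.0671	1
male	27	80.7599422506292	0.06745	1
male	28	80.677209167566	0.0678	1
male	29	80.5943687995359	0.06815	1
male	30	80.511420937719	0.0685	1
male	31	80.4283653727535	0.06885	1
male	32	80.3452018947333	0.0692	1
male	33	80.2619302932065	0.06955	1
male	34	80.1785503571737	0.0699	1
male	35	80.0950618750862	0.07025	1
male	36	80.011464634844	0.0706	1
male	37	79.9277584237941	0.07095	1
male	38	79.843943028729	0.0713	1
male	39	79.7600182358844	0.07165	1
male	40	79.6759838309376	0.072	1
male	41	79.5918395990059	0.07235	1
male	42	79.5075853246444	0.0727	1
male	43	79.4232207918444	0.07305	1
male	44	79.3387457840313	0.0734	1
male	45	79.2541600840632	0.07375	1
male	46	79.1694634742286	0.0741	1
male	47	79.0846557362446	0.07445	1
male	48	78.9997366512553	0.0748	1
male	49	78.9147059998297	0.07515	1
male	50	78.8295635619598	0.0755	1
male	51	78.7443091170587	0.07585	1
male	52	78.6589424439588	0.0762	1
male	53	78.5734633209099	0.07655	1
male	54	78.487871525577	0.0769	1
male	55	78.4021668350389	0.07725	1
male	56	78.3163490257857	0.0776	1
male	57	78.2304178737171	0.07795	1
male	58	78.1443731541407	0.0783	1
male	59	78.0582146417694	0.07865	1
male	60	77.9719421107202	0.079	1
male	61	77.8855553345117	0.07935	1
male	62	77.7990540860622	0.0797	1
male	63	77.7124381376879	0.08005	1
male	64	77.6257072611008	0.0804	1
male	65	77.5388612274066	0.08075	1
male	66	77.4518998071028	0.0811	1
male	67	77.3648227700766	0.08145	1
male	68	77.277629885603	0.0818	1
male	69	77.1903209223426	0.08215	1
male	70	77.1028956483397	0.0825	1
male	71	77.0153538310201	0.08285	1
male	72	76.9276952371892	0.0832	1
male	73	76.8399196330297	0.08355	1
male	74	76.7520267840999	0.0839	1
male	75	76.6640164553312	0.08425	1
male	76	76.5758884110262	0.0846	1
male	77	76.4876424148566	0.08495	1
male	78	76.3992782298611	0.0853	1
male	79	76.3107956184432	0.08565	1
male	80	76.2221943423691	0.086	1
male	81	76.1334741627657	0.08635	1
male	82	76.0446348401182	0.0867	1
male	83	75.955676134268	0.08705	1
male	84	75.8665978044109	0.0874	1
male	85	75.7773996090944	0.08775	1
male	86	75.6880813062157	0.0881	1
male	87	75.5986426530198	0.08845	1
male	88	75.509083406097	0.0888	1
male	89	75.4194033213807	0.08915	1
male	90	75.3296021541451	0.0895	1
male	91	75.2396796590034	0.08985	1
male	92	75.1496355899051	0.0902	1
male	93	75.0594697001341	0.09055	1
male	94	74.969181742306	0.0909	1
male	95	74.8787714683664	0.09125	1
female	18	82.3943648748791	0.0643	1
female	19	82.3131643643537	0.06465	1
female	20	82.2318591671312	0.065	1
female	21	82.1504490806321	0.06535	1
female	22	82.068933901754	0.0657	1
female	23	81.9873134268695	0.06605	1
female	24	81.905587451825	0.0664	1
female	25	81.8237557719387	0.06675	1
female	26	81.7418181819991	0.0671	1
female	27	81.659774476263	0.06745	1
female	28	81.5776244484541	0.0678	1
female	29	81.495367891761	0.06815	1
female	30	81.4130045988357	0.0685	1
female	31	81.3305343617917	0.06885	1
female	32	81.2479569722022	0.0692	1
female	33	81.1652722210985	0.06955	1
female	34	81.0824798989682	0.0699	1
female	35	80.9995797957535	0.07025	1
female	36	80.916571700849	0.0706	1
female	37	80.8334554031006	0.07095	1
female	38	80.7502306908031	0.0713	1
female	39	80.6668973516989	0.07165	1
female	40	80.5834551729756	0.072	1
female	41	80.499903941265	0.07235	1
female	42	80.4162434426404	0.0727	1
female	43	80.3324734626153	0.07305	1
female	44	80.2485937861418	0.0734	1
female	45	80.1646041976079	0.07375	1
female	46	80.0805044808365	0.0741	1
female	47	79.9962944190832	0.07445	1
female	48	79.9119737950343	0.0748	1
female	49	79.8275423908052	0.07515	1
female	50	79.7429999879385	0.0755	1
female	51	79.6583463674018	0.07585	1
female	52	79.5735813095862	0.0762	1
female	53	79.4887045943043	0.07655	1
female	54	79.403716000788	0.0769	1
female	55	79.3186153076869	0.07725	1
female	56	79.2334022930665	0.0776	1
female	57	79.1480767344059	0.07795	1
female	58	79.0626384085959	0.0783	1
female	59	78.9770870919373	0.07865	1
female	60	78.8914225601391	0.079	1
female	61	78.8056445883157	0.07935	1
female	62	78.719752950986	0.0797	1
female	63	78.6337474220707	0.08005	1
female	64	78.5476277748906	0.0804	1
female	65	78.4613937821646	0.08075	1
female	66	78.3750452160075	0.0811	1
female	67	78.2885818479283	0.08145	1
female	68	78.2020034488279	0.0818	1
female	69	78.1153097889974	0.08215	1
female	70	78.0285006381156	0.0825	1
female	71	77.9415757652476	0.08285	1
female	72	77.854534938842	0.0832	1
female	73	77.7673779267295	0.08355	1
female	74	77.6801044961204	0.0839	1
female	75	77.5927144136029	0.08425	1
female	76	77.5052074451406	0.0846	1
female	77	77.4175833560707	0.08495	1
female	78	77.3298419111018	0.0853	1
female	79	77.2419828743119	0.08565	1
female	80	77.1540060091463	0.086	1
female	81	77.065911078415	0.08635	1
female	82	76.9776978442914	0.0867	1
female	83	76.8893660683094	0.08705	1
female	84	76.8009155113618	0.0874	1
female	85	76.7123459336976	0.08775	1
female	86	76.6236570949205	0.0881	1
female	87	76.534848753986	0.08845	1
female	88	76.4459206692	0.0888	1
female	89	76.3568725982157	0.08915	1
female	90	76.2677042980323	0.0895	1
female	91	76.1784155249922	0.08985	1
female	92	76.089006034779	0.0902	1
female	93	75.9994755824151	0.09055	1
female	94	75.9098239222597	0.0909	1
female	95	75.8200508080065	0.09125	1
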