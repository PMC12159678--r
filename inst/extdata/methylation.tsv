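chrom	start	end	name	coverage	strand	mod_fraction
toy1	2003	2004	CpG0001	25	+	0.84
toy1	2010	2011	CpG0002	25	+	0.84
toy1	2017	2018	CpG0003	30	+	0.8
toy1	2026	2027	CpG0004	27	+	0.851851851851852
toy1	2037	2038	CpG0005	37	+	0.837837837837838
toy1	2038	2039	CpG0006	34	+	0.882352941176471
toy1	2043	2044	CpG0007	28	+	0.75
toy1	2044	2045	CpG0008	34	+	0.823529411764706
toy1	2045	2046	CpG0009	28	+	0.892857142857143
toy1	2062	2063	CpG0010	36	+	0.861111111111111
toy1	2064	2065	CpG0011	22	+	0.863636363636364
toy1	2072	2073	CpG0012	40	+	0.825
toy1	2074	2075	CpG0013	26	+	0.846153846153846
toy1	2075	2076	CpG0014	21	+	0.952380952380952
toy1	2077	2078	CpG0015	22	+	0.818181818181818
toy1	2084	2085	CpG0016	24	+	0.75
toy1	2101	2102	CpG0017	33	+	0.818181818181818
toy1	2128	2129	CpG0018	42	+	0.785714285714286
toy1	2134	2135	CpG0019	28	+	0.75
toy1	2136	2137	CpG0020	28	+	0.857142857142857
toy1	2137	2138	CpG0021	24	+	0.875
toy1	2139	2140	CpG0022	31	+	0.903225806451613
toy1	2147	2148	CpG0023	29	+	0.96551724137931
toy1	2151	2152	CpG0024	29	+	0.827586206896552
toy1	2163	2164	CpG0025	26	+	0.884615384615385
toy1	2188	2189	CpG0026	25	+	0.76
toy1	2190	2191	CpG0027	30	+	0.833333333333333
toy1	2204	2205	CpG0028	32	+	0.90625
toy1	2205	2206	CpG0029	38	+	0.842105263157895
toy1	2237	2238	CpG0030	20	+	0.65
toy1	2244	2245	CpG0031	27	+	0.740740740740741
toy1	2251	2252	CpG0032	33	+	0.939393939393939
toy1	2253	2254	CpG0033	35	+	0.857142857142857
toy1	2254	2255	CpG0034	30	+	0.633333333333333
toy1	2262	2263	CpG0035	31	+	0.967741935483871
toy1	2265	2266	CpG0036	39	+	0.897435897435897
toy1	2267	2268	CpG0037	28	+	0.857142857142857
toy1	2274	2275	CpG0038	26	+	0.730769230769231
toy1	2275	2276	CpG0039	30	+	0.766666666666667
toy1	2277	2278	CpG0040	41	+	0.926829268292683
toy1	2287	2288	CpG0041	29	+	0.96551724137931
toy1	2297	2298	CpG0042	31	+	0.806451612903226
toy1	2320	2321	CpG0043	38	+	0.842105263157895
toy1	2324	2325	CpG0044	35	+	0.828571428571429
toy1	2327	2328	CpG0045	31	+	0.806451612903226
toy1	2342	2343	CpG0046	34	+	0.911764705882353
toy1	2350	2351	CpG0047	26	+	0.846153846153846
toy1	2360	2361	CpG0048	27	+	0.925925925925926
toy1	2364	2365	CpG0049	27	+	0.777777777777778
toy1	2371	2372	CpG0050	24	+	0.958333333333333
toy1	2372	2373	CpG0051	32	+	0.90625
toy1	2386	2387	CpG0052	27	+	0.777777777777778
toy1	2390	2391	CpG0053	29	+	0.793103448275862
toy1	2394	2395	CpG0054	36	+	0.75
toy1	2420	2421	CpG0055	24	+	0.75
toy1	2451	2452	CpG0056	35	+	0.8
toy1	2463	2464	CpG0057	29	+	0.896551724137931
toy1	2464	2465	CpG0058	27	+	0.851851851851852
toy1	2465	2466	CpG0059	24	+	0.583333333333333
toy1	2469	2470	CpG0060	22	+	0.909090909090909
toy1	2474	2475	CpG0061	38	+	0.789473684210526
toy1	2494	2495	CpG0062	23	+	0.869565217391304
toy1	2502	2503	CpG0063	33	+	0.848484848484849
toy1	2507	2508	CpG0064	39	+	0.82051282051282
toy1	2517	2518	CpG0065	40	+	0.875
toy1	2533	2534	CpG0066	32	+	0.8125
toy1	2539	2540	CpG0067	35	+	0.828571428571429
toy1	2549	2550	CpG0068	26	+	0.846153846153846
toy1	2565	2566	CpG0069	24	+	0.916666666666667
toy1	2582	2583	CpG0070	28	+	0.75
toy1	2589	2590	CpG0071	28	+	0.821428571428571
toy1	2590	2591	CpG0072	29	+	0.931034482758621
toy1	2601	2602	CpG0073	31	+	0.774193548387097
toy1	2606	2607	CpG0074	33	+	0.818181818181818
toy1	2607	2608	CpG0075	30	+	0.8
toy1	2628	2629	CpG0076	28	+	0.857142857142857
toy1	2638	2639	CpG0077	37	+	0.891891891891892
toy1	2639	2640	CpG0078	26	+	0.923076923076923
toy1	2641	2642	CpG0079	29	+	0.931034482758621
toy1	2647	2648	CpG0080	33	+	0.727272727272727
toy1	2652	2653	CpG0081	35	+	0.914285714285714
toy1	2663	2664	CpG0082	23	+	0.826086956521739
toy1	2666	2667	CpG0083	29	+	0.896551724137931
toy1	2670	2671	CpG0084	24	+	0.75
toy1	2682	2683	CpG0085	27	+	0.777777777777778
toy1	2685	2686	CpG0086	21	+	0.857142857142857
toy1	2686	2687	CpG0087	19	+	0.894736842105263
toy1	2688	2689	CpG0088	28	+	0.892857142857143
toy1	2702	2703	CpG0089	24	+	0.833333333333333
toy1	2703	2704	CpG0090	37	+	0.918918918918919
toy1	2710	2711	CpG0091	31	+	0.903225806451613
toy1	2724	2725	CpG0092	24	+	0.916666666666667
toy1	2736	2737	CpG0093	25	+	0.76
toy1	2739	2740	CpG0094	26	+	0.730769230769231
toy1	2752	2753	CpG0095	35	+	0.885714285714286
toy1	2756	2757	CpG0096	29	+	0.896551724137931
toy1	2760	2761	CpG0097	27	+	0.851851851851852
toy1	2771	2772	CpG0098	25	+	0.84
toy1	2785	2786	CpG0099	33	+	0.878787878787879
toy1	2787	2788	CpG0100	27	+	0.888888888888889
toy1	2790	2791	CpG0101	30	+	0.9
toy1	2794	2795	CpG0102	30	+	0.766666666666667
toy1	2796	2797	CpG0103	33	+	0.727272727272727
toy1	2797	2798	CpG0104	26	+	0.923076923076923
toy1	2798	2799	CpG0105	27	+	0.888888888888889
toy1	2839	2840	CpG0106	33	+	0.727272727272727
toy1	2849	2850	CpG0107	17	+	0.823529411764706
toy1	2853	2854	CpG0108	28	+	0.892857142857143
toy1	2864	2865	CpG0109	24	+	0.875
toy1	2865	2866	CpG0110	24	+	0.708333333333333
toy1	2866	2867	CpG0111	26	+	0.961538461538462
toy1	2882	2883	CpG0112	29	+	1
toy1	2890	2891	CpG0113	37	+	0.891891891891892
toy1	2896	2897	CpG0114	32	+	0.875
toy1	2899	2900	CpG0115	30	+	0.866666666666667
toy1	2907	2908	CpG0116	31	+	0.741935483870968
toy1	2912	2913	CpG0117	33	+	0.878787878787879
toy1	2917	2918	CpG0118	29	+	0.931034482758621
toy1	2918	2919	CpG0119	37	+	0.864864864864865
toy1	2940	2941	CpG0120	32	+	0.8125
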