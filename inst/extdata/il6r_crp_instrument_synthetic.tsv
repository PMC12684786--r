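variant_id	chromosome	base_pair_location	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n
1:154094140:A:C	1	154094140	C	A	0.1688	-0.0258	0.004037	1.649e-10	575531
1:154096947:A:C	1	154096947	C	A	0.3568	-0.0358	0.002039	5.2e-69	575531
1:154127715:A:C	1	154127715	C	A	0.4156	0.0882	0.0136	8.856e-11	575531
1:154154811:A:C	1	154154811	C	A	0.486	-0.0395	0.001484	4.287e-156	575531
1:154166653:A:C	1	154166653	C	A	0.2611	0.1017	0.0115	9.278e-19	575531
1:154234546:A:C	1	154234546	C	A	0.4803	0.0737	0.004558	8.294e-59	575531
1:154251297:A:C	1	154251297	C	A	0.3605	-0.0386	0.001077	2.605e-281	575531
1:154348236:A:C	1	154348236	C	A	0.4859	-0.0103	0.001741	3.296e-09	575531
1:154367372:A:C	1	154367372	C	A	0.4671	-0.0857	0.002941	1.127e-186	575531
1:154391963:A:C	1	154391963	C	A	0.4879	-0.0575	0.007226	1.757e-15	575531
1:154395934:A:C	1	154395934	C	A	0.077	-0.0977	0.002785	1.323e-269	575531
1:154418504:A:C	1	154418504	C	A	0.2732	0.043	0.0009537	9.99988867182683e-321	575531
1:154445735:A:C	1	154445735	C	A	0.2791	-0.0297	0.00239	1.87e-35	575531
rs2228145	1	154426264	C	A	0.401	-0.0993	0.002202	9.99988867182683e-321	575531
1:154505380:A:C	1	154505380	C	A	0.1229	-0.0913	0.008366	9.966e-28	575531
1:154516355:A:C	1	154516355	C	A	0.1722	-0.0673	0.002281	2.513e-191	575531
1:154572803:A:C	1	154572803	C	A	0.4565	-0.1061	0.005515	1.764e-82	575531
1:154584717:A:C	1	154584717	C	A	0.3778	-0.1175	0.01084	2.237e-27	575531
1:154602609:A:C	1	154602609	C	A	0.1102	0.0254	0.002382	1.511e-26	575531
1:154630302:A:C	1	154630302	C	A	0.0916	0.0499	0.008408	2.942e-09	575531
1:154652595:A:C	1	154652595	C	A	0.3083	-0.0517	0.001467	4.551e-272	575531
1:154665946:A:C	1	154665946	C	A	0.153	-0.1077	0.0159	1.256e-11	575531
1:154666333:A:C	1	154666333	C	A	0.294	-0.1127	0.008843	3.343e-37	575531
1:154682832:A:C	1	154682832	C	A	0.4325	-0.0602	0.001505	9.99988867182683e-321	575531
1:154722007:A:C	1	154722007	C	A	0.3815	-0.0304	0.001169	4.333e-149	575531
1:154733729:A:C	1	154733729	C	A	0.181	-0.0922	0.004451	2.566e-95	575531
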