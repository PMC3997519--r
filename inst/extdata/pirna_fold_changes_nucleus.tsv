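#feature	aag2	pop	log2fc
PIR5650	0	12.22396229	inf
PIR59291	0	8.149308193	inf
PIR8200	0	2.394752846	inf
PIR54642	0	2.251782527	inf
PIR249348	0	1.215247713	inf
PIR8813	0	0.750594176	inf
PIR48167	0	0.714851596	inf
PIR35224	0	0.679109016	inf
PIR37716	0	0.643366436	inf
PIR44728	0	0.536138697	inf
PIR260343	0	0.464653537	inf
PIR86373	0	0.393168378	inf
PIR214814	0	0.357425798	inf
PIR210808	0.042309408	1.322475452	4.966118624
PIR239381	0.042309408	0.536138697	3.663555854
PIR35218	0.042309408	0.500396117	3.564020181
PIR54535	0.042309408	0.357425798	3.078593354
PIR7660	0.084618817	0.571881277	2.756665259
PIR72436	0.761569349	4.503565054	2.564020181
PIR59286	0.126928225	0.428910958	1.756665259
PIR75737	0.507712899	1.429703192	1.493630853
PIR65192	0.719259941	2.001584469	1.47655734
PIR2224	8.800356922	23.8760433	1.439929833
PIR32635	0.423094083	1.036534814	1.292718159
PIR31042	0.338475266	0.822079335	1.280227215
PIR224625	0.634641124	1.393960612	1.135176882
PIR22527	0.169237633	0.357425798	1.078593354
PIR202518	0.761569349	0.357425798	-1.091331648
PIR236686	1.396210473	0.357425798	-1.965800766
PIR61400	0.423094083	0.107227739	-1.980300335
PIR60123	0.423094083	0.07148516	-2.565262836
PIR197269	1.057735207	0	-inf
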