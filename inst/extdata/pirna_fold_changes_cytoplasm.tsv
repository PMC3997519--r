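#feature	aag2	pop	log2fc
PIR8200	0	10.93765991	inf
PIR59291	0	10.04478972	inf
PIR5650	0	2.678610591	inf
PIR8813	0	2.008957943	inf
PIR249348	0	1.785740394	inf
PIR31228	0	1.67413162	inf
PIR32635	0.199082548	1.339305296	2.7500462
PIR19840	0.99541274	3.906307112	1.972438621
PIR42038	0.398165096	1.339305296	1.7500462
PIR82944	0.796330192	2.678610591	1.7500462
PIR58103	1.99082548	0.781261422	-1.349489474
PIR69440	2.588073124	0.892870197	-1.535356019
PIR238999	2.189908028	0.669652648	-1.709385419
PIR236686	18.51467696	4.910786084	-1.914643494
PIR65192	140.950444	35.37998156	-1.994182821
PIR202518	6.370641536	1.45091407	-2.134476583
PIR51286	3.185320768	0.446435099	-2.834916301
PIR60603	3.782568412	0.223217549	-4.082843814
PIR37488	1.99082548	0.111608775	-4.156844396
PIR197269	6.171558988	0	-inf
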