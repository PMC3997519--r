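#feature	aag2	pop	fold	log2fc
miR-2946	56.84	602.34	10.60	3.41
miR-125-5p	15.05	147.15	9.78	3.29
miR-100	36.78	295.49	8.03	3.01
miR-9c-5p	23.40	142.96	6.11	2.61
let-7	25.08	130.40	5.20	2.38
miR-2941	25.08	126.21	5.03	2.33
miR-2765	315.96	1315.95	4.16	2.06
miR-277-3p	28.42	75.37	2.65	1.41
miR-7	23.40	57.42	2.45	1.29
bantam-3p	511.55	1168.20	2.28	1.19
miR-9c-3p	50.15	101.69	2.03	1.02
miR-34-5p	1721.87	814.69	-2.11	-1.08
miR-281-5p	4236.14	1875.22	-2.26	-1.18
miR-263a-5p	616.87	218.33	-2.83	-1.50
miR-989	2495.88	801.53	-3.11	-1.64
miR-34-3p	35.11	10.17	-3.45	-1.79
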