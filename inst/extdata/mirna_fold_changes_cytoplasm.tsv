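#feature	aag2	pop	fold	log2fc
miR-125-5p	19.08	2007.64	105.22	6.72
miR-100	81.41	2550.82	31.33	4.97
miR-71-3p	225.14	2724.54	12.10	3.60
miR-2946	21.62	246.83	11.41	3.51
let-7	185.71	1666.48	8.97	3.17
miR-14	597.83	4448.40	7.44	2.90
miR-285	15.26	88.83	5.82	2.54
miR-996	25.44	108.48	4.26	2.09
miR-281-3p	26.71	101.40	3.80	1.92
miR-2941	125.93	406.40	3.23	1.69
miR-9c-5p	34.34	110.05	3.20	1.68
miR-276-3p	2297.20	7077.83	3.08	1.62
miR-988-3p	315.45	643.80	2.04	1.03
miR-2945-3p	99.21	48.74	-2.04	-1.03
miR-278-5p	80.13	36.16	-2.22	-1.15
miR-278-3p	716.13	316.79	-2.26	-1.18
miR-2b	558.40	246.04	-2.27	-1.18
miR-8-3p	2992.97	1256.15	-2.38	-1.25
miR-283	20239.77	8318.25	-2.43	-1.28
miR-998	4909.85	1774.17	-2.77	-1.47
miR-190	290.01	103.76	-2.79	-1.48
miR-8-5p	432.47	150.14	-2.88	-1.53
miR-317	86651.18	27885.26	-3.11	-1.64
miR-1175-3p	48.34	14.94	-3.24	-1.69
bantam-5p	3027.32	738.13	-4.10	-2.04
miR-263a-5p	2243.78	492.08	-4.56	-2.19
miR-305-5p	26004.39	4216.51	-6.17	-2.62
miR-263a-3p	87.77	12.58	-6.98	-2.80
miR-1174	118.29	15.72	-7.52	-2.91
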