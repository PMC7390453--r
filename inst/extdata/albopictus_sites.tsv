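population	lat	lon	marine	aerial
Mauritius	-20.43	57.39	2.68	41
Colombo-1	6.94	79.95	*	*
Colombo-2	6.96	79.94	9.62	101
Chiang Mai	18.54	98.60	0	48
Selangor	3.14	101.69	3	257
Pahang	3.82	103.33	3.2	5
Johor	1.49	103.74	3.28	18
Singapore	1.35	103.82	2.07	408
Ho Chi Minh City	10.78	106.70	0.44	109
Christmas Island	-10.45	105.69	1.91	2
Jakarta	-6.21	106.85	1.09	185
Bandung	-6.91	107.61	0.53	21
Bali	-8.65	115.22	1.24	100
Guangzhou	23.13	113.26	0.24	338
Hong Kong	22.32	114.17	3.87	355
Taiwan	22.99	120.21	7.24	65
Manila	14.60	120.98	1.56	193
Matsuyama	33.84	132.77	1.97	12
Vanuatu	-17.73	168.32	0.71	28
Fiji	-17.80	177.42	0.84	43
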