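population	lat	lon	marine	aerial
Jeddah	21.49	39.19	7.92	194
Colombo	6.98	79.93	9.62	101
Bangkok	13.76	100.50	0.17	326
Kuala Lumpur	3.14	101.69	3	257
Singapore	1.35	103.82	2.64	408
Ho Chi Minh City	10.78	106.70	0.43	109
Nha Trang	12.21	109.22	5.26	7
Yogyakarta	-7.80	110.37	0.44	29
Bali	-8.75	115.17	1.24	100
Taiwan	22.99	120.21	7.25	65
Cairns	-16.92	145.77	1.86	56
Townsville	-19.25	146.77	2.25	16
New Caledonia	-22.28	166.46	1.24	13
Vanuatu	-17.73	168.32	0.71	28
Fiji	-17.80	177.42	0.85	43
Kiribati	1.33	172.98	0.8	3
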