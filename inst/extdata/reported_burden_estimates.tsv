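gene	region	births	births_lo	births_hi	carriers_thousands	patients	patients_lo	patients_hi
PEX7	US	11.8	9.3	14.6	1130	190	150	235
GNPAT	US	5.0	3.7	6.4	732	80	59	104
AGPS	US	0.3	0.1	0.4	168	4	2	7
FAR1	US	0.6	0.3	0.9	246	9	5	14
PEX5	US	0.3	0.2	0.5	189	5	3	9
TOTAL	US	18	14	23	2465	288	219	368
PEX7	EU5	14.2	11.4	17.4	1395	240	192	293
GNPAT	EU5	7.4	5.7	9.4	1006	125	96	158
AGPS	EU5	0.5	0.3	0.8	269	9	5	14
FAR1	EU5	0.1	0.0	0.2	126	2	1	4
PEX5	EU5	0.4	0.2	0.6	228	6	3	11
TOTAL	EU5	23	18	28	3024	382	297	479
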