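# thermoscan reduced nearest-neighbor parameter set
# version=nn-lite-1.0
# units: dH kcal/mol, dS kcal/(mol*K), dG37 kcal/mol
[STACK]
AU/AU	-6.8200	-0.0189908
AU/UA	-9.3800	-0.0266968
AU/CG	-11.4000	-0.0295341
AU/GC	-10.4800	-0.0270837
AU/GU	-3.2100	-0.0085765
AU/UG	-8.8100	-0.0240206
UA/AU	-7.6900	-0.0205062
UA/UA	-6.8200	-0.0189908
UA/CG	-12.4400	-0.0325326
UA/GC	-10.4400	-0.0268580
UA/GU	-6.9900	-0.0184427
UA/UG	-9.2600	-0.0253103
CG/AU	-10.4400	-0.0268580
CG/UA	-10.4800	-0.0270837
CG/CG	-13.3900	-0.0326616
CG/GC	-10.6400	-0.0266968
CG/GU	-5.6100	-0.0135418
CG/UG	-12.1100	-0.0322425
GC/AU	-12.4400	-0.0325326
GC/UA	-11.4000	-0.0295341
GC/CG	-14.8800	-0.0369499
GC/GC	-13.3900	-0.0326616
GC/GU	-8.3300	-0.0219249
GC/UG	-12.5900	-0.0325004
GU/AU	-9.2600	-0.0253103
GU/UA	-8.8100	-0.0240206
GU/CG	-12.5900	-0.0325004
GU/GC	-12.1100	-0.0322425
GU/GU	-9.2600	-0.0282444
GU/UG	-13.4700	-0.0414961
UG/AU	-6.9900	-0.0184427
UG/UA	-3.2100	-0.0085765
UG/CG	-8.3300	-0.0219249
UG/GC	-5.6100	-0.0135418
UG/GU	-6.3000	-0.0190231
UG/UG	-5.1000	-0.0154764
[HAIRPIN]
3	5.4000
4	5.6000
5	5.7000
6	5.4000
7	6.0000
8	5.5000
9	6.4000
10	6.5136
11	6.6164
12	6.7103
13	6.7966
14	6.8765
15	6.9510
16	7.0206
17	7.0860
18	7.1476
19	7.2059
20	7.2612
21	7.3139
22	7.3640
23	7.4120
24	7.4579
25	7.5019
26	7.5442
27	7.5849
28	7.6241
29	7.6620
30	7.6986
[LOOP]
1	3.8000
2	2.8000
3	3.2000
4	3.6000
5	4.0000
6	4.4000
7	4.5663
8	4.7103
9	4.8373
10	4.9510
11	5.0538
12	5.1476
13	5.2339
14	5.3139
15	5.3883
16	5.4579
17	5.5233
18	5.5849
19	5.6432
20	5.6986
21	5.7512
22	5.8014
23	5.8493
24	5.8952
25	5.9392
26	5.9815
27	6.0222
28	6.0615
29	6.0993
30	6.1359
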