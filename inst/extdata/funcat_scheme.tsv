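category	label	weight
1	METABOLISM	2401
2	ENERGY	522
3	CELL CYCLE AND DNA PROCESSING	971
4	TRANSCRIPTION	1921
5	PROTEIN SYNTHESIS	399
6	PROTEIN FATE (folding modification destination)	2187
7	PROTEIN WITH BINDING FUNCTION OR COFACTOR REQUIREMENT (structural or catalytic)	7330
8	REGULATION OF METABOLISM AND PROTEIN FUNCTION	972
9	CELLULAR TRANSPORT TRANSPORT FACILITIES AND TRANSPORT ROUTES	2078
10	CELLULAR COMMUNICATION/SIGNAL TRANSDUCTION MECHANISM	3143
11	CELL RESCUE DEFENSE AND VIRULENCE	656
12	INTERACTION WITH THE ENVIRONMENT	1212
13	SYSTEMIC INTERACTION WITH THE ENVIRONMENT	1454
14	TRANSPOSABLE ELEMENTS VIRAL AND PLASMID PROTEINS	9
15	CELL FATE	1180
16	DEVELOPMENT (Systemic)	939
17	BIOGENESIS OF CELLULAR COMPONENTS	769
18	CELL TYPE DIFFERENTIATION	317
19	TISSUE DIFFERENTIATION	313
20	ORGAN DIFFERENTIATION	491
21	SUBCELLULAR LOCALIZATION	8467
22	CELL TYPE LOCALIZATION	232
23	TISSUE LOCALIZATION	261
24	ORGAN LOCALIZATION	542
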