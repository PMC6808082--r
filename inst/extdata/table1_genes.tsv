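Gene	Beginning	Ending	Length	Orientation	Description	Part_of_CNV	Read_Depth	DE	P_Value
KS_00451	27406	28674	1268	Reverse	GRAVITROPIC IN THE LIGHT 1-like	No	0	-0.43	0.00
KS_00452	35728	36696	968	Reverse	IRK-interacting protein	No	0	-2.62	0.05
KS_00453	37839	41640	3801	Reverse	Nitroreductase family	No	0	0.74	0.00
KS_00454	43124	47121	3997	Forward	Arginase 1, mitochondrial	56.1 kb	2.86	2.23	0.00
KS_00455	47240	52651	5411	Reverse	Protein NRT1/ PTR FAMILY 7.2-like	56.1 kb	2.86	0.72	0.58
KS_00456	63014	72467	9453	Forward	tRNA N6-adenosine threonylcarbamoyltransferase	56.1 kb and 32.7 kb	3.49	3.03	0.00
KS_00457	72617	73531	914	Reverse	Golgin subfamily A member 6-like	56.1 kb and 32.7 kb	3.49	-3.18	0.00
KS_00458	76342	81181	4839	Forward	DNA repair protein RAD51	56.1 kb and 32.7 kb	3.46	1.33	0.00
KS_00459	82421	84836	2415	Forward	Transketolase, chloroplastic-like	56.1 kb and 32.7 kb	3.29	3.83	0.00
KS_00460	91663	97214	5551	Forward	3-phosphoshikimate 1-carboxyvinyltransferase 2 (EPSPS)	56.1 kb and 32.7 kb	3.12	4.01	0.00
KS_00461	106901	109241	2340	Forward	NAD-dependent epimerase	No	0	2.52	0.00
KS_00462	106975	110332	3357	Reverse	Uncharacterized protein	No	0	2.54	0.06
KS_00463	113504	114006	502	Reverse	DUF861	No	0	0.05	0.85
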