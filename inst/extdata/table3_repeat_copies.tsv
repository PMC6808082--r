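Line	Replicate	repeat_56kb	repeat_32kb	MGE
7710	1	NA	NA	3.9
7710	2	NA	NA	5.5
7710	3	NA	NA	4.7
M32	1	5.4	1.8	16.2
M32	2	5.1	1.9	17.4
M32	3	5.1	1.7	18.2
M32	4	5.3	1.7	14.1
M32	5	6.9	2.1	17.7
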