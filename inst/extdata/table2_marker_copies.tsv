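Line	Replicate	M1	M2	M3	M4	M5	M6	M7	M8	M9	M10	M11
7710	1	0.9	0.7	NA	1.1	1.6	1.1	1.3	1.2	0.7	1.9	0.8
7710	2	0.7	0.7	NA	1.0	1.5	1.2	1.4	1.4	0.9	1.7	1.2
7710	3	0.7	0.6	NA	0.9	1.0	1.2	0.7	1.3	1.0	1.6	1.1
M32	1	0.9	0.7	9.5	6.1	11.3	11.2	11.3	11.5	1.0	NA	1.0
M32	2	0.8	0.7	9.5	6.0	12.6	12.1	12.4	13.3	1.0	NA	1.1
M32	3	0.7	0.6	7.6	3.2	10.9	11.1	11.0	11.7	1.0	NA	1.0
M32	4	0.7	0.7	8.1	5.1	10.8	9.9	10.4	9.9	0.9	NA	0.9
M32	5	1.2	1.0	14.2	10.0	20.3	19.0	19.6	20.0	1.3	NA	1.4
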