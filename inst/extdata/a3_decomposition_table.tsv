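compound	dE_water	sigma_water	TdS_water	dE_protein	sigma_protein	TdS_protein	ddG	ddE_printed	sigma_printed	TddS_printed
2a>3a	-88.9	0.5	-6.1	-78.7	2.0	-1.4	5.4	10.1	2.0	4.8
2d>3d	-88.6	0.5	-6.0	-90.3	3.3	-9.5	1.8	-1.7	3.3	-3.5
2g>3g	-88.5	0.5	-5.6	-79.4	1.2	-2.1	5.6	9.1	1.3	3.5
2j1>3j1	9.8	0.7	1.3	0.5	2.3	-8.6	0.6	-9.3	2.4	-9.9
2j2>3j2	8.0	0.6	-0.3	7.9	1.7	-8.0	7.6	-0.1	1.8	-7.7
2m1>3m1	-93.2	0.8	-8.7	-93.5	5.4	-10.0	1.1	-0.3	5.5	-1.4
2m2>3m2	-91.6	0.8	-7.2	-94.5	1.3	-11.7	1.5	-2.9	1.5	-4.4
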