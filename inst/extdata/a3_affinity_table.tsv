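compound	pose	qualifier	exp_ddG	-0.74	-0.64	-0.59	-0.54	-0.49	-0.44	-0.34
a	none	=	5.2	7.7	6.5	5.9	5.4	4.4	4.4	3.7
d	none	=	-3.1	4.2	3.0	2.4	1.8	0.3	0.9	0.3
g	none	=	8.4	6.7	6.2	5.9	5.6	4.8	5.0	4.5
j	1	>	12.9	2.5	1.5	1.1	0.6	0.2	0.0	-0.1
j	2	>	12.9	10.0	8.8	8.2	7.6	6.4	6.4	5.1
m	1	=	1.0	1.4	1.1	1.1	1.1	1.0	1.4	2.1
m	2	=	1.0	-0.1	1.0	1.3	1.5	1.9	1.4	1.2
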