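class	ps_mean	mean_SC3-5-7	mean_SC3-5-8	mean_SC3-5-12	mean_SC3-5-13	mean_SC3-5-14	sig_SC3-5-7	sig_SC3-5-8	sig_SC3-5-12	sig_SC3-5-13	sig_SC3-5-14	screened
ACE	5.89	7.24	43.24	46.39	15.73	24.56	0	1	1	1	1	1
NAE	6.31	5.38	4.9	5.47	6.36	6	0	0	0	0	0	0
ALD	33.3	52.02	19.24	13.64	35.82	29.44	1	0	-1	0	0	1
ALC	16.8	17.17	14.78	11.4	15.54	16.05	0	0	0	0	0	0
KET	19.8	9.48	6.79	6.35	13	10.06	-1	-1	-1	-1	-1	1
ACD	0.24	0.38	0.36	0.3	0.23	1.02	0	0	0	0	0	0
SDC	1.5	2.22	7.79	7.25	4.84	6.99	0	1	1	1	1	1
TER	1.4	1.01	0.73	0.97	1.36	1.31	0	-1	0	0	0	1
AHA	2.08	1.69	0.58	1.2	1.96	1.27	0	-1	0	0	0	1
OTH	6.42	3.51	1.63	2.62	4.36	3.36	0	-1	-1	0	-1	1
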