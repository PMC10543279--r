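scale	n1	mean1	sd1	n2	mean2	sd2	p_reported	d_reported
PVT	821	105.97	15.81	248	101.62	15.37	1.22e-4	0.28
LSWMT	821	98.74	14.30	248	94.70	14.52	1.35e-4	0.28
DCCST	821	95.21	14.77	248	90.95	13.68	2.87e-5	0.30
PCPST	821	91.62	22.42	248	84.66	22.14	1.89e-6	0.31
PSMT	821	98.94	15.43	248	95.20	15.36	8.57e-4	0.24
Fluid	821	92.72	17.00	248	85.98	16.32	3.09e-8	0.40
Total	821	97.18	17.20	248	90.72	16.95	2.61e-7	0.38
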