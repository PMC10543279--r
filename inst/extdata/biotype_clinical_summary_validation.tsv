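scale	n1	mean1	sd1	n2	mean2	sd2	p_reported	d_reported
RS_HI	89	18.64	4.27	41	22.22	5.16	4.97e-4	0.68
RS_Total	89	45.14	6.79	41	48.82	6.42	3.82e-3	0.56
PIQ	89	107.41	15.28	41	100.89	11.59	0.01	0.48
CPRS_IH	89	4.94	2.27	41	6.33	2.75	8.67e-3	0.55
CPRS_HIndex	89	12.96	4.18	41	15.23	4.66	0.01	0.51
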