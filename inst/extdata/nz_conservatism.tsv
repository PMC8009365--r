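clade	rate_single	sd_single	rate_multiple	sd_multiple	p_single	p_multiple	sig_single	sig_multiple
Chionochloa	0.73	0.05	1.05	0.07	0.40	0.44	no	no
Coprosma	0.56	0.04	0.74	0.05	0.58	0.85	no	no
Melicytus	0.18	0.03	0.55	0.07	0.98	0.98	yes	yes
Myrsine	0.27	0.06	0.55	0.05	0.00	0.35	no	no
Poa X	0.62	0.05	0.72	0.07	0.69	0.95	no	yes
Pseudopanax	0.31	0.05	0.54	0.04	0.83	0.32	no	no
Rytidosperma A	0.86	0.13	1.29	0.16	0.81	0.22	no	no
Rytidosperma B	0.57	0.12	0.86	0.14	0.58	0.89	no	no
Veronica	0.49	0.04	0.78	0.05	0.70	0.56	no	no
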