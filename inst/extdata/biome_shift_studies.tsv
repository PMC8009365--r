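study	location	lineage	clade_size	specialists_n	specialists_pct	multiple_biomes	shift_count	censored	shift_rate	nz	description
Cardillo et al. 2017	Australia	Hakea	151	113	75	yes	47	no	0.31	no	frequent
Crisp et al. 2009	Southern Hemisphere	45 taxa	11000	NA	NA	no	396	no	0.04	no	rare
Cruz et al. 2017	Brazil	Cryptanthus	48	NA	NA	no	4	no	0.08	no	rare
Gagnon et al. 2019	Global	Caesalpinia Group	168	144	86	yes	24	no	0.14	no	strong conservatism
Gamisch et al. 2016	Madagascar	Bulbophyllum	30	26	87	yes	21	no	0.7	no	exceptionally high
Holstein & Renner 2011	Africa	Coccinia	27	NA	NA	no	6	no	0.22	no	frequent
Jara-Arancio et al. 2014	Western South America	Leucornye	17	13	76	no	2	no	0.11	no	low conservatism
Simon et al. 2009	South America	Andira	25	20	80	no	2	no	0.04	no	frequent
Simon et al. 2009	South America	Lupinus	94	93	99	no	1	no	0.01	no	frequent
Simon et al. 2009	South America	Mimosa	255	223	87	no	11	no	0.04	no	frequent
Simon et al. 2009	South America	Microlicieae	60	54	90	no	1	no	0.02	no	frequent
Spriggs et al. 2015	Northern Hemisphere	Viburnum	138	NA	NA	no	10	yes	0.07	no	more common than expected
Toon et al. 2015	Australia	Triondiinae	66	51	77	yes	15	yes	0.23	no	multiple
Weeks et al. 2014	Global	Anacardiaceae	169	164	97	yes	74	no	0.44	no	extremely common
Weeks et al. 2014	Global	Burseraceae	136	132	97	yes	11	no	0.08	no	few
Zizka et al. 2020	The Tropics	Bombacoideae	174	73	42	yes	84	no	0.48	no	common
This study	New Zealand	Chionochloa	22	12	55	yes	23	no	1.04	yes	NA
This study	New Zealand	Coprosma	54	30	56	yes	40	no	0.74	yes	NA
This study	New Zealand	Melicytus	11	7	64	yes	6	no	0.54	yes	NA
This study	New Zealand	Myrsine	11	5	45	yes	6	no	0.54	yes	NA
This study	New Zealand	Poa X	29	20	69	yes	21	no	0.72	yes	NA
This study	New Zealand	Pseudopanax	13	4	31	yes	7	no	0.54	yes	NA
This study	New Zealand	Rytidosperma A	7	3	43	yes	9	no	1.29	yes	NA
This study	New Zealand	Rytidosperma B	7	4	57	yes	6	no	0.86	yes	NA
This study	New Zealand	Veronica	51	23	45	yes	40	no	0.78	yes	NA
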