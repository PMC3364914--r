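species	n_nonpalm	n_palm	printed_proportion	printed_direction
Acalypha cuneata	252	64	0.80	palm
Acidoton nicaraguensis	862	117	0.88	nonpalm
Aniba guianensis	40	14	0.74	palm
Bertiera guianensis	5	4	0.56	palm
Calyptranthes bipennis	66	4	0.94	nonpalm
Calyptranthes sedosa	66	4	0.94	nonpalm
Discophora guianensis	64	3	0.96	nonpalm
Endlicheria dori	74	4	0.95	nonpalm
Eugenia pusilliflora	216	18	0.92	nonpalm
Garcinia brasiliensis	40	0	1.00	nonpalm
Geonoma aspidiifolia	721	71	0.91	nonpalm
Guarea fistulosa	349	37	0.90	nonpalm
Guatteria scalarinervia	95	7	0.93	nonpalm
Hyospathe elegans	120	11	0.92	nonpalm
Inga auristellae	635	86	0.88	nonpalm
Leonia glycycarpa	173	15	0.92	nonpalm
Licania nervifina	65	3	0.96	nonpalm
Lacistema nena	41	0	1.00	nonpalm
Matisia oblongifolia	1537	322	0.83	palm
Miconia multispicata	36	16	0.69	palm
Miconia tipica	204	54	0.79	palm
Mollinedia killipii	89	4	0.96	nonpalm
Neea bajio	197	14	0.93	nonpalm
Otoba glycycarpa	44	16	0.73	palm
Pentagonia spathicalyx	28	12	0.70	palm
Picramnia mini	30	0	1.00	nonpalm
Piper obchic	1702	183	0.90	nonpalm
Pourouma bicolor	550	67	0.89	nonpalm
Pouteria trilocularis	45	1	0.98	nonpalm
Sorocea muriculata	262	26	0.91	nonpalm
Tococa guianensis	1	6	0.14	palm
Unonopsis veneficiorum	330	33	0.91	nonpalm
Hippocrateaceae atenumembra	179	18	0.91	nonpalm
Eugenia smedcomun	195	20	0.91	nonpalm
Solanaceae plata	3	4	0.43	palm
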