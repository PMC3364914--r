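species	dbh_1_10	dbh_10_15	dbh_ge_15
Iriartea deltoidea	493	292	1520
Astrocaryum chambira	0	3	94
Oenocarpus bataua	0	3	98
Socratea exorrhiza	15	11	3
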