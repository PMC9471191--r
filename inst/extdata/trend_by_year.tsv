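family	year	concordant_n	proportion_pct
overall	2015	4225	84.45
overall	2016	5847	85.82
overall	2017	7002	86.03
first_line	2015	4797	95.88
first_line	2016	6569	96.42
first_line	2017	7874	96.74
optimized	2015	204	26.29
optimized	2016	269	27.14
optimized	2017	338	27.93
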