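label	numerator	denominator	reported_pct
overall_concordance	17074	19955	85.56
first_line_initiation	19240	19955	96.42
optimized_concordance	811	2977	27.24
optimized_uptake	2829	19240	14.70
discordant_switch	447	1528	29.25
discordant_addon	390	1301	29.98
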