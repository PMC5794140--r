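class	area1_landcover_pct	area1_relative_accuracy_pct	area2_landcover_pct	area2_relative_accuracy_pct
bare_soil	10.9	90.0	7.7	96.0
depression	6.0	83.3	7.5	87.2
field	50.1	86.3	71.2	81.0
forest	0.4	33.3	0.5	25.0
homestead	2.8	91.5	5.2	95.2
shrubland	29.1	50.0	6.4	11.4
water	0.2	93.8	1.1	100
urban	0.5	NA	0.4	NA
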