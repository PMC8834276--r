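name	total_area_ha	established_year	guardians_count	guard_stations	reported_annual_visitors	operating_days	availability_hours	average_visit_hours
Lar national park	35765	2001	14	4	36000	109	8	8
Jajrud PA	74811	1982	28	7	50000	365	8	8
Tangeh Vashi natural monument	3650	2011	4	1	300000	155	8	8
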