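site_name	use_type	class_label	area_ha	percent_within_group	group_total_ha	group_percent_of_site
Lar national park	extensive	1	442.9	44.3	1000.0	2.8
Lar national park	extensive	2	557.1	55.7	1000.0	2.8
Jajrud PA	extensive	1	286.2	39.3	728.0	0.1
Jajrud PA	extensive	2	441.8	60.7	728.0	0.1
Jajrud PA	intensive	1	11.0	55.8	19.8	0.03
Jajrud PA	intensive	2	8.8	44.2	19.8	0.03
Tangeh Vashi natural monument	extensive	1	1.8	35.0	5.3	0.1
Tangeh Vashi natural monument	extensive	2	3.4	65.0	5.3	0.1
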