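site_name	use_type	class_label	area_m2	space_per_visitor_m2
Lar national park	extensive	1	4430300	2500
Lar national park	extensive	2	5566100	2500
Jajrud PA	extensive	1	2858000	2500
Jajrud PA	extensive	2	4422000	2500
Jajrud PA	intensive	1	112600	1500
Jajrud PA	intensive	2	88500	1500
Tangeh Vashi natural monument	extensive	1	18500	2500
Tangeh Vashi natural monument	extensive	2	34700	2500
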