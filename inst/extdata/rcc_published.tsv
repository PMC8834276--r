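site_name	zone	rcc_daily	rcc_annual
Lar national park	ET1	1	109
Lar national park	ET2	2	218
Jajrud PA	ET1	4	1460
Jajrud PA	ET2	6	2190
Jajrud PA	IT1	1	365
Jajrud PA	IT2	2	730
Tangeh Vashi natural monument	ET1	1	155
Tangeh Vashi natural monument	ET2	3	465
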