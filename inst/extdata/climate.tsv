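site_name	station_name	elevation_m	latitude	longitude	code	magnitude	unit	total_mt
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf1	12	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf2	3	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf3	4	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf4	12	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf5	57	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf6	2	days	365
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf7	2717	hours	NA
Lar national park	Damavand Synoptic	2051	35.7167	52.05	Cf8	42	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf1	19	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf2	15	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf3	10	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf4	25	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf5	116	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf6	3	days	365
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf7	2833	hours	NA
Jajrud PA	Lavasan Synoptic	1863	35.8317	51.6425	Cf8	49	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf1	15	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf2	2	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf3	4	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf4	11	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf5	144	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf6	3	days	365
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf7	3010	hours	NA
Tangeh Vashi natural monument	Firuzkooh Synoptic	1976	35.75	52.7333	Cf8	24	days	365
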