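site_name	code	percent
Lar national park	Cf7	21
Jajrud PA	Cf7	19
Tangeh Vashi natural monument	Cf7	18
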