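dimension	item_id	label	n	mean	rank
environmental-physical	EP01	Destruction of the habitat and ecosystem	33	4.32	1
environmental-physical	EP02	Extinction of biologically valuable species	33	4.26	2
environmental-physical	EP03	Increase in wildlife hunting	33	3.21	13
environmental-physical	EP04	Change of the wildlife species diet and migration path	33	3.16	14
environmental-physical	EP05	Reduction and loss of vegetation covers	33	4.11	3
environmental-physical	EP06	Change in the ecosystem function	33	3.08	15
environmental-physical	EP07	Decrease in biodiversity	33	3.86	4
environmental-physical	EP08	Decrease in ecosystem services	33	3.72	6
environmental-physical	EP09	Decrease in natural resources	33	3.76	5
environmental-physical	EP10	Increase in environmental pollution	33	3.68	7
environmental-physical	EP11	Decrease in groundwater reservoirs and change in surface water regime	33	3.57	8
environmental-physical	EP12	Increase in climate change	33	3.48	9
environmental-physical	EP13	Change in biogeochemical cycles	33	2.63	21
environmental-physical	EP14	Increase in the water evaporation level	33	2.68	20
environmental-physical	EP15	Increase in the soil erosion level	33	3.31	11
environmental-physical	EP16	Increase in LULC changes for tourism infrastructure	33	3.35	10
environmental-physical	EP17	Disturbance of landscape	33	3.27	12
environmental-physical	EP18	Increase in garbage per visitor	33	2.94	17
environmental-physical	EP19	Changes in the quality of local services	33	3.02	16
environmental-physical	EP20	Increase in abrupt environmental crises	33	2.77	19
environmental-physical	EP21	Increase in congestion in roads and public places	33	2.85	18
socio-cultural	SC01	Increase in crime and insecurity	33	3.84	1
socio-cultural	SC02	Increase in accidents	33	2.71	8
socio-cultural	SC03	Destruction of cultural-historical and ancient monuments	33	3.46	4
socio-cultural	SC04	Changes in the culture of local communities	33	3.31	5
socio-cultural	SC05	Dissatisfaction in local communities	33	3.57	3
socio-cultural	SC06	Increase in cultural invasions	33	3.68	2
socio-cultural	SC07	Changes in quality of life standards	33	3.16	6
socio-cultural	SC08	Increase in diseases	33	2.88	7
economic-institutional	EI01	Increase in taxes on land, buildings, and other structures	33	3.62	2
economic-institutional	EI02	Increase in inflation	33	3.78	1
economic-institutional	EI03	Increase in the demand for public services	33	2.53	7
economic-institutional	EI04	Increase in the demand for economic infrastructure	33	2.67	6
economic-institutional	EI05	Increase in tourism costs	33	3.11	4
economic-institutional	EI06	Increase in seasonal employees in tourism	33	2.95	5
economic-institutional	EI07	Increase in economic pressures on households	33	3.34	3
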