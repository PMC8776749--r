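adm0_code	name	kind
9	Anguilla	no_data
14	Aruba	no_data
16	Ashmore_and_Cartier_Islands	no_data
74578	Azores_Islands	no_data
22	Baker_Island	no_data
25	Bassas_da_India	no_data
32	Bird_Island	no_data
36	Bouvet_Island	no_data
38	British_Indian_Ocean_Territory	no_data
54	Christmas_Island	no_data
55	Clipperton_Island	no_data
56	Cocos_(Keeling)_Islands	no_data
80	Europa_Island	no_data
88	French_Southern_and_Antarctic_Territories	no_data
96	Glorioso_Island	no_data
98	Greenland	no_data
104	Guernsey	no_data
109	Heard_Island_and_McDonald_Islands	no_data
112	Howland_Island	no_data
120	Isle_of_Man	no_data
127	Jarvis_Island	no_data
128	Jersey	no_data
129	Johnston_Atoll	no_data
131	Juan_de_Nova_Island	no_data
134	Kingman_Reef	no_data
136	Kuril_islands	no_data
151	Madeira_Islands	no_data
161	Mayotte	no_data
164	Midway_Island	no_data
174	Navassa_Island	no_data
176	Netherlands_Antilles	no_data
184	Norfolk_Island	no_data
185	Northern_Mariana_Islands	no_data
190	Palmyra_Atoll	no_data
193	Paracel_Islands	no_data
197	Pitcairn	no_data
207	Saint_Helena	no_data
216	Scarborough_Reef	no_data
218	Senkaku_Islands	no_data
228	South_Georgia_and_the_South_Sandwich_Islands	no_data
230	Spratly_Islands	no_data
234	Svalbard_and_Jan_Mayen_Islands	no_data
247	Tromelin_Island	no_data
251	Turks_and_Caicos_Islands	no_data
258	United_States_Virgin_Islands	no_data
265	Wake_Island	no_data
95	Gibraltar	no_data
110	Holy_See	no_data
146	Liechtenstein	no_data
102	Abyei	disputed
2	Aksai_Chin	disputed
15	Arunachal_Pradesh	disputed
52	China/India	disputed
40760	Hala'ib_Triangle	disputed
61013	Ilemi_Triangle	disputed
40781	Jammu_and_Kashmir	disputed
40762	Ma'tan_al-Sarra	disputed
81	Falkland_Islands_(Malvinas)	disputed
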