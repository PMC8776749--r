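faostat_code	faostat_name	gaez_crop	no_longer_reported
15	Wheat	Wheat	FALSE
27	Rice_paddy	Rice	FALSE
56	Maize	Maize	FALSE
83	Sorghum	Sorghum	FALSE
79	Millet	Millet	FALSE
44	Barley	Barley	FALSE
71	Rye	Other_cereals	FALSE
75	Oats	Other_cereals	FALSE
89	Buckwheat	Other_cereals	FALSE
92	Quinoa	Other_cereals	FALSE
94	Fonio	Other_cereals	FALSE
97	Triticale	Other_cereals	FALSE
101	Canary_seed	Other_cereals	FALSE
103	Grain_mixed	Other_cereals	FALSE
108	Cereals_nes	Other_cereals	FALSE
116	Potatoes	Potato_&_Sweet_potato	FALSE
122	Sweet_potatoes	Potato_&_Sweet_potato	FALSE
125	Cassava	Cassava	FALSE
135	Yautia_(cocoyam)	Yams_and_other_roots	FALSE
136	Taro_(cocoyam)	Yams_and_other_roots	FALSE
137	Yams	Yams_and_other_roots	FALSE
149	Roots_and_tubers_nes	Yams_and_other_roots	FALSE
157	Sugar_beet	Sugarbeet	FALSE
156	Sugar_cane	Sugarcane	FALSE
176	Beans_dry	Pulses	FALSE
181	Broad_beans_dry	Pulses	FALSE
187	Peas_dry	Pulses	FALSE
191	Chick_peas	Pulses	FALSE
195	Cow_peas_dry	Pulses	FALSE
197	Pigeon_peas	Pulses	FALSE
201	Lentils	Pulses	FALSE
203	Bambara_beans	Pulses	FALSE
211	Pulses_nes	Pulses	FALSE
236	Soybeans	Soybean	FALSE
270	Rapeseed	Rapeseed	FALSE
267	Sunflower_seed	Sunflower	FALSE
242	Groundnuts_with_shell	Groundnut	FALSE
254	Oil_Palm_Fruit	Oil_palm_fruit	FALSE
260	Olives	Olives	FALSE
328	Seed_Cotton	Cotton	FALSE
826	Tobacco_unmanufactured	Tobacco	FALSE
486	Bananas	Banana	FALSE
489	Plantains	Banana	FALSE
656	Coffee_green	Stimulants	FALSE
661	Cocoa_beans	Stimulants	FALSE
667	Tea	Stimulants	FALSE
671	Mate	Stimulants	FALSE
358	Cabbages	Vegetables	FALSE
366	Artichokes	Vegetables	FALSE
367	Asparagus	Vegetables	FALSE
372	Lettuce_and_chicory	Vegetables	FALSE
373	Spinach	Vegetables	FALSE
378	Cassave_Leaves	Vegetables	FALSE
388	Tomatoes	Vegetables	FALSE
393	Cauliflowers_and_broccoli	Vegetables	FALSE
394	Pumpkins_squash_gourds	Vegetables	FALSE
397	Cucumbers_and_gherkins	Vegetables	FALSE
399	Eggplants_(aubergines)	Vegetables	FALSE
401	Chillies_peppers_green	Vegetables	FALSE
402	Onions_shallots_green	Vegetables	FALSE
403	Onions_dry	Vegetables	FALSE
406	Garlic	Vegetables	FALSE
407	Leeks	Vegetables	FALSE
414	Beans_green	Vegetables	FALSE
417	Peas_green	Vegetables	FALSE
420	Vegetables_legum._nes	Vegetables	FALSE
423	String_beans	Vegetables	FALSE
426	Carrots_and_turnips	Vegetables	FALSE
430	Okra	Vegetables	FALSE
446	Maize_green	Vegetables	FALSE
449	Mushrooms_and_truffles	Vegetables	FALSE
459	Chicory_roots	Vegetables	FALSE
461	Carobs	Vegetables	FALSE
463	Vegetables_fresh_nes	Vegetables	FALSE
689	Chillies_and_peppers_dry	Vegetables	FALSE
216	Brazil_nuts_with_shell	Crops_NES	FALSE
217	Cashew_nuts_with_shell	Crops_NES	FALSE
220	Chestnut	Crops_NES	FALSE
221	Almonds_with_shell	Crops_NES	FALSE
222	Walnuts_with_shell	Crops_NES	FALSE
223	Pistachios	Crops_NES	FALSE
224	Kola_nuts	Crops_NES	FALSE
225	Hazelnuts_with_shell	Crops_NES	FALSE
226	Areca_nuts	Crops_NES	FALSE
234	Nuts_nes	Crops_NES	FALSE
249	Coconuts	Crops_NES	FALSE
263	Karite_nuts_(sheanuts)	Crops_NES	FALSE
275	Tung_nuts	Crops_NES	FALSE
299	Melonseed	Crops_NES	FALSE
310	Kapok_Fruit	Crops_NES	FALSE
490	Oranges	Crops_NES	FALSE
495	Tangerines	Crops_NES	FALSE
497	Lemons_and_limes	Crops_NES	FALSE
507	Grapefruit_(incl._pomelos)	Crops_NES	FALSE
512	Fruit_citrus_nes	Crops_NES	FALSE
515	Apples	Crops_NES	FALSE
521	Pears	Crops_NES	FALSE
523	Quinces	Crops_NES	FALSE
526	Apricots	Crops_NES	FALSE
530	Cherries_sour	Crops_NES	FALSE
531	Cherries	Crops_NES	FALSE
534	Peaches_and_nectarines	Crops_NES	FALSE
536	Plums_and_sloes	Crops_NES	FALSE
541	Fruit_stone_nes	Crops_NES	FALSE
542	Fruit_pome_nes	Crops_NES	FALSE
544	Strawberries	Crops_NES	FALSE
547	Raspberries	Crops_NES	FALSE
549	Gooseberries	Crops_NES	FALSE
550	Currants	Crops_NES	FALSE
552	Blueberries	Crops_NES	FALSE
554	Cranberries	Crops_NES	FALSE
558	Berries_nes	Crops_NES	FALSE
560	Grapes	Crops_NES	FALSE
567	Watermelons	Crops_NES	FALSE
568	Melons_other	Crops_NES	FALSE
569	Figs	Crops_NES	FALSE
571	Mangoes_guavas	Crops_NES	FALSE
572	Avocados	Crops_NES	FALSE
574	Pineapples	Crops_NES	FALSE
577	Dates	Crops_NES	FALSE
587	Persimmons	Crops_NES	FALSE
591	Cashewapple	Crops_NES	FALSE
592	Kiwi_fruit	Crops_NES	FALSE
600	Papayas	Crops_NES	FALSE
603	Fruit_tropical_fresh_nes	Crops_NES	FALSE
619	Fruit_fresh_nes	Crops_NES	FALSE
161	Sugar_crops_nes	Crops_NES	FALSE
205	Vetches	Crops_NES	FALSE
210	Lupins	Crops_NES	FALSE
265	Castor_oil_seed	Crops_NES	FALSE
277	Jojoba_Seeds	Crops_NES	FALSE
280	Safflower_seed	Crops_NES	FALSE
289	Sesame_seed	Crops_NES	FALSE
292	Mustard_seed	Crops_NES	FALSE
296	Poppy_seed	Crops_NES	FALSE
305	Tallowtree_Seeds	Crops_NES	FALSE
333	Linseed	Crops_NES	FALSE
336	Hempseed	Crops_NES	FALSE
339	Oilseeds_nes	Crops_NES	FALSE
677	Hops	Crops_NES	FALSE
687	Pepper_(piper_spp.)	Crops_NES	FALSE
692	Vanilla	Crops_NES	FALSE
693	Cinnamon_(canella)	Crops_NES	FALSE
698	Cloves	Crops_NES	FALSE
702	Nutmeg_mace_cardamoms	Crops_NES	FALSE
711	Anise_badian_fennel	Crops_NES	FALSE
720	Ginger	Crops_NES	FALSE
723	Spices_nes	Crops_NES	FALSE
748	Peppermint	Crops_NES	FALSE
754	Pyrethrum_dried	Crops_NES	FALSE
773	Flax_fibre_and_tow	Crops_NES	FALSE
777	Hemp_tow_waste	Crops_NES	FALSE
780	Jute	Crops_NES	FALSE
782	Bastfibres_other	Crops_NES	FALSE
788	Ramie	Crops_NES	FALSE
789	Sisal	Crops_NES	FALSE
800	Agave_fibres_nes	Crops_NES	FALSE
809	Manila_fibre_(abaca)	Crops_NES	FALSE
821	Fibre_crops_nes	Crops_NES	FALSE
644	Cabbages_for_fodder	Fodder_crop	TRUE
645	Pumpkins_for_fodder	Fodder_crop	TRUE
646	Turnips_for_fodder	Fodder_crop	TRUE
647	Beets_for_fodder	Fodder_crop	TRUE
648	Carrots_for_fodder	Fodder_crop	TRUE
649	Swedes_for_fodder	Fodder_crop	TRUE
655	Vegetables_&_roots_fodder	Fodder_crop	TRUE
651	Forage_products	Fodder_crop	TRUE
636	Forage_&_silage_maize	Fodder_crop	TRUE
637	Forage_&_silage_sorghum	Fodder_crop	TRUE
638	Forage_&_silage_rye_grass	Fodder_crop	TRUE
639	Forage_&_silage_grasses_nes	Fodder_crop	TRUE
640	Forage_&_silage_clover	Fodder_crop	TRUE
641	Forage_&_silage_alfalfa	Fodder_crop	TRUE
642	Forage_&_silage_green_oilsd	Fodder_crop	TRUE
643	Forage_&_silage_legumes	Fodder_crop	TRUE
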