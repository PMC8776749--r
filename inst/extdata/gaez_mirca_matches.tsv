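gaez_crop	mirca_crops	one_to_one	removal_order
Banana	Others_perennial	FALSE	3
Barley	Barley	TRUE	18
Cassava	Cassava	TRUE	11
Cotton	Cotton	TRUE	4
Crops_NES	Others_perennial;Others_annual	FALSE	2
Fodder_crop	Fodder_grasses	FALSE	2
Groundnut	Groundnut	TRUE	6
Maize	Maize	TRUE	20
Millet	Millet	TRUE	16
Oil_palm_fruit	Oil_palm	TRUE	8
Olives	Others_perennial	FALSE	3
Other_cereals	Rye;Millet	FALSE	17
Potato_&_Sweet_potato	Potatoes	TRUE	12
Pulses	Pulses	TRUE	5
Rapeseed	Canola	TRUE	7
Rice	Rice	TRUE	19
Sorghum	Sorghum	TRUE	15
Soybean	Soybeans	TRUE	14
Stimulants	Others_annual	FALSE	1
Sugarbeet	Sugarbeet	TRUE	9
Sugarcane	Sugarcane	TRUE	10
Sunflower	Sunflower	TRUE	13
Tobacco	Others_annual	FALSE	1
Vegetables	Others_annual	FALSE	1
Wheat	Wheat	TRUE	21
Yams_and_other_roots	Others_annual	FALSE	1
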