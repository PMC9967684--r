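item_id,name,group,vitd_per_100g,portion_g_1,portion_g_2,portion_g_3
milk_fortified,Fortified whole cow milk,dairy & beverages,1.0,125,250,330
milk_powder,Whole powdered milk (reconstituted),dairy & beverages,2.5,100,200,
yogurt_fortified,Fortified light yogurt,dairy & beverages,0.8,110,220,
cheese_hard,Hard cheese,dairy & beverages,1.3,20,40,60
soy_drink_fortified,Fortified soy drink,dairy & beverages,0.75,200,250,
egg_boiled,Boiled egg,eggs,2.0,50,60,120
egg_fried,Pan-fried egg with fat,eggs,2.2,55,65,
fish_fatty,Fatty fish (sardine; mackerel),fish & sea products,11.0,80,130,200
fish_canned,Canned or smoked fish,fish & sea products,7.0,50,90,150
fish_white,White fish,fish & sea products,1.5,100,150,200
cod_liver,Cod liver,fish & sea products,54.0,15,30,
shellfish,Shellfish,fish & sea products,4.0,60,100,150
meat_red,Red meat,meat products,0.5,80,120,180
poultry,Poultry,meat products,0.3,90,140,200
liver_organ,Organ meat (liver),meat products,1.1,75,120,
margarine_fortified,Fortified margarine,fat products,7.5,5,10,20
butter,Butter,fat products,1.2,5,10,20
oil_fortified,Fortified vegetable oil,fat products,5.0,5,10,15
cereal_fortified,Fortified breakfast cereal,breakfast cereals,4.2,30,45,60
biscuit_moroccan,Moroccan biscuit,bakery & Moroccan biscuit,0.4,25,50,75
viennoiserie,Viennoiserie,bakery & Moroccan biscuit,0.6,50,80,
chocolate_milk,Milk chocolate bar,chocolate & cacao,0.55,20,45,
cocoa_fortified,Fortified cocoa drink powder,chocolate & cacao,2.4,10,20,30
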