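item_id,restaurant,item_name,major_category,sub_category,serving_size,serving_unit,calories_kcal,sodium_mg,sugars_g,satfat_g
ex001,chain_a,classic poutine,entrees,poutine,250,g,1835,3373,5,43
ex002,chain_a,pepperoni slice,entrees,pizza,160,g,420,890,4,7
ex003,chain_a,side garden salad,sides,salads,120,g,70,85,3,0.5
ex004,chain_a,dipping sauce,sides,dips,28,g,120,240,2,1.5
ex005,chain_b,chocolate shake,beverages,milkshakes/floats,500,ml,690,300,75,12
ex006,chain_b,sparkling water,beverages,water,500,ml,0,10,0,0
ex007,chain_b,2% milk,beverages,plain milk,250,ml,110,115,12,3
ex008,chain_b,iced coffee,beverages,coffee and tea,,ml,180,65,28,3.5
ex009,chain_c,brownie sundae,desserts,frozen desserts,210,g,640,260,52,11
ex010,chain_c,butter croissant,desserts,baked goods,65,g,270,240,6,7
ex011,chain_c,chicken wings,starters,wings,300,g,860,1950,1,9
ex012,chain_c,loaded nachos,starters,miscellaneous,,g,1120,2310,4,14
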