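rice_products: cereals_tubers
wheat_products: cereals_tubers
tubers: cereals_tubers
leafy_vegetables: vegetables
root_vegetables: vegetables
gourd_vegetables: vegetables
mushrooms: vegetables
fruits: fruits
pork: meat
poultry: meat
beef_lamb: meat
organ_meats: meat
fish: fish_seafood
shellfish: fish_seafood
eggs: eggs
dairy: dairy
soy_products: legumes_nuts
nuts: legumes_nuts
cooking_oils: oils_fats
seasonings: none
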