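item	group
breads_item_a	breads
breads_item_b	breads
chocolate_sweets_item_a	chocolate_sweets
chocolate_sweets_item_b	chocolate_sweets
eggs_item_a	eggs
eggs_item_b	eggs
blue_fish_item_a	blue_fish
blue_fish_item_b	blue_fish
white_fish_item_a	white_fish
white_fish_item_b	white_fish
soybean_products_item_a	soybean_products
soybean_products_item_b	soybean_products
milk_item_a	milk
milk_item_b	milk
pizza_hamburger_item_a	pizza_hamburger
pizza_hamburger_item_b	pizza_hamburger
yellow_orange_fruit_item_a	yellow_orange_fruit
yellow_orange_fruit_item_b	yellow_orange_fruit
white_fruit_item_a	white_fruit
white_fruit_item_b	white_fruit
purple_fruit_item_a	purple_fruit
purple_fruit_item_b	purple_fruit
red_pink_fruit_item_a	red_pink_fruit
red_pink_fruit_item_b	red_pink_fruit
red_vegetables_item_a	red_vegetables
red_vegetables_item_b	red_vegetables
dairy_item_a	dairy
dairy_item_b	dairy
white_meat_item_a	white_meat
white_meat_item_b	white_meat
sushi_item_a	sushi
sushi_item_b	sushi
meat_soup_item_a	meat_soup
meat_soup_item_b	meat_soup
unprocessed_red_meat_item_a	unprocessed_red_meat
unprocessed_red_meat_item_b	unprocessed_red_meat
noodles_item_a	noodles
noodles_item_b	noodles
green_tea_item_a	green_tea
green_tea_item_b	green_tea
soda_item_a	soda
soda_item_b	soda
other_drinks_item_a	other_drinks
other_drinks_item_b	other_drinks
rice_cake_item_a	rice_cake
rice_cake_item_b	rice_cake
white_rice_item_a	white_rice
white_rice_item_b	white_rice
mixed_rice_item_a	mixed_rice
mixed_rice_item_b	mixed_rice
mushrooms_item_a	mushrooms
mushrooms_item_b	mushrooms
other_vegetables_item_a	other_vegetables
other_vegetables_item_b	other_vegetables
kimchi_item_a	kimchi
kimchi_item_b	kimchi
carrots_item_a	carrots
carrots_item_b	carrots
brown_vegetables_item_a	brown_vegetables
brown_vegetables_item_b	brown_vegetables
cruciferous_vegetables_item_a	cruciferous_vegetables
cruciferous_vegetables_item_b	cruciferous_vegetables
pumpkin_item_a	pumpkin
pumpkin_item_b	pumpkin
radishes_item_a	radishes
radishes_item_b	radishes
allium_vegetables_item_a	allium_vegetables
allium_vegetables_item_b	allium_vegetables
green_vegetables_item_a	green_vegetables
green_vegetables_item_b	green_vegetables
potatoes_starch_item_a	potatoes_starch
potatoes_starch_item_b	potatoes_starch
cereal_item_a	cereal
cereal_item_b	cereal
crustacean_item_a	crustacean
crustacean_item_b	crustacean
legumes_item_a	legumes
legumes_item_b	legumes
mollusks_item_a	mollusks
mollusks_item_b	mollusks
coffee_item_a	coffee
coffee_item_b	coffee
seaweed_item_a	seaweed
seaweed_item_b	seaweed
processed_red_meat_item_a	processed_red_meat
processed_red_meat_item_b	processed_red_meat
processed_seafood_item_a	processed_seafood
processed_seafood_item_b	processed_seafood
nuts_item_a	nuts
nuts_item_b	nuts
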