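# Column mapping (canonical name -> column name in the input file) and
# subcategory vocabulary. Both are data: edit to match your export.
columns:
  item_id: item_id
  restaurant: restaurant
  item_name: item_name
  major_category: major_category
  sub_category: sub_category
  serving_size: serving_size
  serving_unit: serving_unit
  calories_kcal: calories_kcal
  sodium_mg: sodium_mg
  sugars_g: sugars_g
  satfat_g: satfat_g

# Controlled vocabulary of subcategories per major category. Seeded from
# subcategories named in published tabulations of Canadian chain-restaurant
# menus; extend freely — the list is configuration, not code.
vocabulary:
  beverages:
    - alcohol
    - plain milk
    - water
    - juices/smoothies
    - milkshakes/floats
    - soft drinks
    - coffee and tea
    - hot chocolate
    - miscellaneous
  desserts:
    - frozen desserts
    - baked goods
    - miscellaneous
  entrees:
    - burgers/sandwiches
    - pizza
    - pasta
    - salads
    - poutine
    - baked goods
    - chicken
    - seafood
    - miscellaneous
  sides:
    - fries and onion rings
    - salads
    - breads
    - dips
    - miscellaneous
  starters:
    - dips
    - fries and onion rings
    - wings
    - miscellaneous
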