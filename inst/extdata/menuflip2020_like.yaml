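# Calibrated recipe for Menu-FLIP-like synthetic menus.
#
# Per-category nutrient amounts are zero-inflated lognormal; `mean` is the
# arithmetic mean of the generating distribution (zeros included) and is the
# calibration target; `sigma` is the log-scale SD. Category-mean targets for
# cells with published values: beverages sugars 38.9 g, desserts sugars
# 29.6 g, entrees sodium 1232 mg, sides sodium 693 mg, starters sodium
# 1588 mg, calories 233/610/665 kcal (beverages/entrees/starters), sat fat
# 9.6/10.1 g (entrees/starters). Remaining cells and all sigmas are
# plausible fill-ins, not authoritative.
n_items: 18760
missing_serving_rate: 0.292

category_mix:
  beverages: 0.27
  desserts: 0.105
  entrees: 0.485
  sides: 0.115
  starters: 0.025

categories:
  beverages:
    sub_mix:
      alcohol: 0.016
      plain milk: 0.016
      water: 0.020
      juices/smoothies: 0.25
      milkshakes/floats: 0.12
      soft drinks: 0.30
      coffee and tea: 0.228
      hot chocolate: 0.05
    serving: {unit: mL, mean: 400, sigma: 0.5}
    serving_correlation: 0
    nutrients:
      calories_kcal: {mean: 233, sigma: 0.8, zero_p: 0.02}
      sodium_mg:     {mean: 60,  sigma: 0.9, zero_p: 0.05}
      sugars_g:      {mean: 38.9, sigma: 0.7, zero_p: 0.0}
      satfat_g:      {mean: 3.5, sigma: 1.0, zero_p: 0.10}
  desserts:
    sub_mix:
      frozen desserts: 0.35
      baked goods: 0.45
      miscellaneous: 0.20
    serving: {unit: g, mean: 140, sigma: 0.6}
    serving_correlation: 0
    nutrients:
      calories_kcal: {mean: 390, sigma: 0.7, zero_p: 0.0}
      sodium_mg:     {mean: 250, sigma: 0.8, zero_p: 0.0}
      sugars_g:      {mean: 29.6, sigma: 0.7, zero_p: 0.0}
      satfat_g:      {mean: 8,   sigma: 0.9, zero_p: 0.0}
  entrees:
    sub_mix:
      burgers/sandwiches: 0.28
      pizza: 0.14
      pasta: 0.10
      salads: 0.08
      poutine: 0.05
      baked goods: 0.04
      chicken: 0.16
      seafood: 0.07
      miscellaneous: 0.08
    serving: {unit: g, mean: 330, sigma: 0.5}
    serving_correlation: 0
    nutrients:
      calories_kcal: {mean: 610, sigma: 0.6, zero_p: 0.0}
      sodium_mg:     {mean: 1232, sigma: 0.8, zero_p: 0.0}
      sugars_g:      {mean: 8,   sigma: 0.9, zero_p: 0.05}
      satfat_g:      {mean: 9.6, sigma: 0.8, zero_p: 0.0}
  sides:
    sub_mix:
      fries and onion rings: 0.40
      salads: 0.20
      breads: 0.20
      dips: 0.05
      miscellaneous: 0.15
    serving: {unit: g, mean: 150, sigma: 0.6}
    serving_correlation: 0
    nutrients:
      calories_kcal: {mean: 400, sigma: 0.7, zero_p: 0.0}
      sodium_mg:     {mean: 693, sigma: 0.8, zero_p: 0.0}
      sugars_g:      {mean: 4,   sigma: 0.9, zero_p: 0.10}
      satfat_g:      {mean: 5,   sigma: 0.9, zero_p: 0.0}
  starters:
    sub_mix:
      dips: 0.20
      fries and onion rings: 0.30
      wings: 0.25
      miscellaneous: 0.25
    serving: {unit: g, mean: 260, sigma: 0.5}
    serving_correlation: 0
    nutrients:
      calories_kcal: {mean: 665, sigma: 0.6, zero_p: 0.0}
      sodium_mg:     {mean: 1588, sigma: 0.8, zero_p: 0.0}
      sugars_g:      {mean: 3,   sigma: 0.9, zero_p: 0.10}
      satfat_g:      {mean: 10.1, sigma: 0.9, zero_p: 0.0}
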