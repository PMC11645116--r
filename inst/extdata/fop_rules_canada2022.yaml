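# Canadian mandatory front-of-package "high-in" labelling rules.
# Version-stamp: Canada Gazette II, July 2022, as reported.
version: "Canada Gazette II, July 2022, as reported"

daily_values:
  sodium_mg: 2300     # CDRR-based sodium daily value
  sugars_g: 100
  satfat_g: 20

# Serving-size bands partition (0, Inf):
#   small    = (0, 30]          -> 10 % DV
#   standard = (30, cutoff)     -> 15 % DV
#   large    = [cutoff, Inf)    -> 30 % DV  (main dish)
# cutoff is 200 g for adults/children >4 y, 170 g for children 1-4 y.
bands:
  small_max_g: 30
  dv_percent:
    small: 10
    standard: 15
    large: 30

profiles:
  adults_children_over4:
    main_dish_cutoff_g: 200
  children_1to4:
    main_dish_cutoff_g: 170
    # Daily values for the 1-4 y profile are not part of the shipped
    # defaults; supply a daily_values override before using this profile
    # for threshold queries.

# Absolute per-nutrient thresholds by band. Stored literally: the sugars
# large-band value is 20 g as promulgated, not 30 % of the 100 g DV.
# Set options.sugars_large_g: 30 to use the %DV-derived variant.
thresholds:
  sodium_mg:   {small: 230, standard: 345, large: 690}
  sugars_g:    {small: 10,  standard: 15,  large: 20}
  satfat_g:    {small: 2,   standard: 3,   large: 6}

options:
  sugars_large_g: null

# Subcategories exempt from assessment regardless of nutrient content.
# The full regulatory exemption criteria are data, not code: edit freely.
exempt_subcategories:
  - {major: beverages, sub: alcohol}
  - {major: beverages, sub: plain milk}
  - {major: beverages, sub: water}
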