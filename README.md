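# menufop

Health Canada's mandatory front-of-package (FOP) labelling regulations
(Canada Gazette II, July 2022) require prepackaged foods that meet or
exceed thresholds for the three *nutrients-of-concern* — sodium, total
sugars and saturated fat — to display a "high-in" FOP symbol starting in
2026. The regulations do not cover restaurant foods. `menufop`
implements the regulatory rules as a reusable classification engine and
an analysis pipeline for *menu* data, so that researchers in nutritional
epidemiology and food-environment profiling can simulate what extending
the policy to the restaurant sector would do: which items would carry a
symbol, for how many nutrients, and how outcomes distribute across menu
categories.

## The classification rule

For an item with stated serving size $s$ (g or mL, treated 1:1), the
applicable threshold band is

$$
\text{band}(s) =
\begin{cases}
\text{small} & s \le 30\ \text{g} \quad (10\,\%\ \text{DV})\\
\text{standard} & 30 < s < c \quad (15\,\%\ \text{DV})\\
\text{large} & s \ge c \quad (30\,\%\ \text{DV, main dish})
\end{cases}
$$

with main-dish cutoff $c = 200$ g for adults and children over 4 y
($c = 170$ g for foods intended solely for children 1–4 y). Daily values
are sodium 2300 mg (the CDRR), total sugars 100 g, saturated fat 20 g.
The absolute thresholds per band are stored literally, as promulgated:

| nutrient | small (10 % DV) | standard (15 % DV) | large (30 % DV) |
|---|---|---|---|
| sodium | 230 mg | 345 mg | 690 mg |
| total sugars | 10 g | 15 g | 20 g |
| saturated fat | 2 g | 3 g | 6 g |

(The sugars large-band value is 20 g in the regulation, not the 30 g
that 30 % of the DV would give; a config switch exposes the %DV-derived
variant.) An item is flagged "high-in" a nutrient when its per-serving
amount **meets or exceeds** the threshold (inclusive comparison, no
rounding). Before any of this, items in exempt subcategories (by
default: beverages/alcohol, beverages/plain milk, beverages/water) are
exempt regardless of nutrient content; non-exempt items lacking a
numeric serving size cannot be banded and are excluded from the main
analysis. The *analytical sample* is assessed + exempt items, with
exempt items counted as "no FOP symbol".

All regulatory constants live in an editable YAML file
(`inst/extdata/fop_rules_canada2022.yaml`); nothing is hard-coded.

## Worked example

```r
library(menufop)
items <- read_menu_table(system.file("extdata", "example_menu.csv",
                                     package = "menufop"))
cfg  <- fop_config()
part <- partition_sample(items, cfg)
part$partition
#>   n_total n_exempt n_excluded_missing_serving n_assessed analytical_n ...
#> 1      12        2                          2          8           10
```

Of 12 items, 2 are exempt (sparkling water, plain milk), 2 lack a
serving size and are excluded, and 8 are assessed. Tabulating symbol
outcomes over the analytical sample of 10:

```r
summarize_symbols(items, part$classified)
#>    category analytical_n n_any pct_any pct1_of_displayers pct2_of_displayers
#> 1   overall           10     7      70                 29                 71
#> 2 beverages            3     1      33                  0                100
#> ...
summarize_nutrient_flags(items, part$classified)
#>    category analytical_n n_sodium pct_sodium n_sugars pct_sugars n_satfat pct_satfat
#> 1   overall           10        4         40        2         20        6         60
```

70 % of the analytical sample would display a symbol; of those
displayers, 29 % flag one nutrient and 71 % two. By nutrient, 40 % are
high-in sodium, 20 % high-in sugars and 60 % high-in saturated fat.
The two items missing serving sizes can still be screened under imposed
bands (15 % DV for desserts/sides, 30 % DV for the rest):

```r
sensitivity_missing_serving(items[is.na(items$serving_size), ], config = cfg)$results
#>   item_id  band flag_sodium flag_sugars flag_satfat n_flags
#> 1   ex008 large       FALSE        TRUE       FALSE       1
#> 2   ex012 large        TRUE       FALSE        TRUE       2
```

Because real chain-restaurant nutrition databases are proprietary, the
package ships a calibrated synthetic generator
(`calibrated_generator_config()`, `generate_menu()`) emulating their
structure — five major categories, right-skewed nutrient distributions,
29.2 % missing serving sizes, ~1.4 % exemption-eligible items — with a
closed-form flag-rate oracle (`expected_flag_rate()`) for validation.
See the methods vignette (`vignettes/menu-fop-methods.Rmd`) for the
model, assumptions and calibration choices.

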