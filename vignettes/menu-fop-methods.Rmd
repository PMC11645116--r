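---
title: "Methods: FOP 'high-in' classification of menu items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FOP 'high-in' classification of menu items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menufop)
```

## The procedure

`menufop` applies Canada's mandatory front-of-package (FOP) "high-in"
labelling rules to restaurant menu items. The per-item procedure is a
three-step flow:

1. **Exemption.** If the item's (major, sub) category pair is in the
   exemption list — by default beverages/alcohol, beverages/plain milk
   and beverages/water — it is `exempt`: it will never display a symbol,
   whatever its composition. Exemption is evaluated *before* the
   serving-size check, because an exempt item needs no serving size; an
   exempt item with a blank serving cell is exempt, not excluded.
2. **Exclusion.** A non-exempt item without a positive numeric serving
   size cannot be placed in a threshold band. Restaurant foods have no
   reference-amount table (the prepackaged-food "serving size or
   reference amount, whichever is greater" pathway does not exist for
   them), so the stated serving is the only denominator; such items are
   `excluded_missing_serving` from the main analysis.
3. **Assessment.** The serving size selects a band — small `(0, 30]` g
   at 10 % DV, standard `(30, c)` g at 15 % DV, large `[c, Inf)` g at
   30 % DV, with main-dish cutoff `c` = 200 g for the adult profile and
   170 g for the children 1–4 y profile. Per nutrient, the item is
   flagged "high-in" when its amount per serving **meets or exceeds**
   the band's absolute threshold. The symbol then lists 1–3 nutrients
   (`n_flags`).

Both band boundaries are inclusive toward their band: 30 g is small,
200 g is large. Where published descriptions of the rule disagree on
whether 200 g itself is a main dish, we follow the threshold summary
table's "200 g or more" wording. Nutrient amounts are compared
unrounded; nutrition-facts rounding rules are out of scope.

## Tunable parameters

All regulatory constants are data, shipped in
`inst/extdata/fop_rules_canada2022.yaml` and loaded by `fop_config()`:

* **Daily values**: sodium 2300 mg (the Chronic Disease Risk Reduction
  level), total sugars 100 g, saturated fat 20 g. The sugars and
  saturated-fat DVs are the values implied by the promulgated 10 % DV
  thresholds (10 g and 2 g).
* **Thresholds** per nutrient × band: sodium 230/345/690 mg, sugars
  10/15/20 g, saturated fat 2/3/6 g. They are stored literally and never
  recomputed from %DV at query time. For sodium and saturated fat the
  stored values equal `dv_percent × DV` exactly; the sugars large-band
  value does **not** (the regulation promulgates 20 g although 30 % of
  the 100 g DV is 30 g). We take the promulgated 20 g as the default and
  expose the %DV-derived variant through `options$sugars_large_g: 30`,
  because both readings are defensible and the choice materially changes
  beverage/dessert flag rates.
* **Age profile**: the children 1–4 y profile is implemented
  structurally (170 g cutoff). Child-specific daily values are not part
  of the shipped defaults; analyses here run the adult profile, and a
  user selecting the child profile for threshold queries should supply a
  `daily_values` override in the YAML.
* **Exemption list**: the regulation defines its exemptions by external
  criteria, of which only a few named subcategories are fixed points in
  menu data; the list is therefore configuration, not code.
* **Units**: serving sizes in mL are treated as numerically equivalent
  to grams (density 1.0), since gram-denominated bands are applied to
  beverages without modification in practice. Files are UTF-8 CSV with
  `.` as decimal mark.

## Denominators and rounding

Three denominator conventions coexist in this kind of tabulation and the
package emits all of them so each is checkable:

* partition percentages (exempt, missing) are on the **total** sample,
  except the assessed share, which is on the total **net of
  exemptions**; these are reported at one decimal;
* the *analytical sample* (assessed + exempt, with exempt items counted
  as "no symbol") is the denominator for the any-symbol percentage and
  the per-nutrient percentages;
* the 1/2/3-nutrient split is additionally reported on
  **symbol-displaying** items (`pct*_of_displayers`).

Reported table percentages are rounded half-up to integers
(`round_half_up()`), not banker's rounding; whether published tables use
half-up or half-to-even is generally undecidable from their text, and
half-up reproduces the standard worked cases (e.g. 10 217 / 13 283 →
77 %, 4 400 / 10 217 → 43 %).

## Descriptive statistics

`descriptive_stats()` reports mean and median per serving with 95 %
intervals by major or submenu category. The mean CI is t-based
(`qt(0.975, n - 1) * sd / sqrt(n)`). No standard closed form exists for
a median CI at these skewed, tied distributions, so we use a seeded
bootstrap percentile interval (1000 resamples by default; the seed is
recorded in rendered reports). Groups with fewer than two non-missing
values return point estimates with `NA` intervals. Missing nutrient
values are dropped per nutrient, not per item.

## Degenerate inputs and edge policies

* A missing nutrient value on an *assessed* item yields `FALSE` for that
  nutrient's flag plus a warning: absence of data cannot demonstrate
  that a threshold is met. The flag is not `NA` because the symbol
  decision is binary in practice.
* In memory, non-assessed items carry all-`FALSE` flags and
  `n_flags = 0`. On disk the two non-assessed states are distinguished:
  exempt rows write explicit `0` flags, excluded rows write empty cells
  ("not assessed" is not the same claim as "assessed, not high-in").
  `read_classified_table()` restores the in-memory convention.
* Empty inputs produce empty tables, not errors; reports render with
  zero counts.
* `select_band()` refuses missing/non-positive servings rather than
  guessing, directing the caller to the exclusion path.

## Sensitivity analysis for missing serving sizes

Items excluded for missing serving sizes can still be screened by
imposing a band per major category: 15 % DV (standard) for desserts and
sides, whose category-mean servings sit below the main-dish cutoff, and
30 % DV (large) for beverages, entrées and starters, whose means sit at
or above it. `sensitivity_missing_serving()` refuses items that do have
a serving size — they belong in the main analysis.

## The synthetic generator

Real chain-restaurant nutrition databases are proprietary, so the
package ships a generator (`generate_menu()`) with a calibrated recipe
(`calibrated_generator_config()`, YAML in
`inst/extdata/menuflip2020_like.yaml`) that emulates their *structure*:

* five major categories with subcategory mixes; the exempt beverage
  subcategories carry enough mass for ≈1.4 % exempt items overall;
* serving sizes and nutrient amounts drawn from zero-inflated lognormal
  distributions — right-skewed and non-negative, which matches the
  reported pattern of category means far above plausible medians; this
  is a modelling convenience, not a claim about any real database's true
  distributions;
* category-specific locations: sodium concentrated in entrées and
  starters, sugars in beverages and desserts. Where a published
  category mean exists (e.g. entrées sodium 1232 mg, beverages sugars
  38.9 g, starters 665 kcal) the generating distribution's mean equals
  it exactly — distributions are parameterised by arithmetic mean and
  log-SD, with the log-mean derived internally — so calibration targets
  are explicit. Cells without a published mean, and all spreads, are
  plausible fill-ins chosen once and documented in the YAML; spreads are
  non-identifiable from published CI widths without per-cell sample
  sizes and are not authoritative.
* serving sizes missing completely at random at rate 0.292 by default;
  a per-category `serving_correlation` (Gaussian copula) exists because
  excluded items may plausibly differ systematically, but the default is
  independence.

`expected_flag_rate()` gives the analytic ground truth in the
independence case: `P(flag) = Σ_band P(serving ∈ band) ×
P(amount ≥ threshold_band)`, each factor a (zero-inflated) lognormal
distribution function, with point masses handled by indicators. A
non-zero copula correlation breaks the factorisation and is refused in
favour of Monte-Carlo estimation.

What passing tests on generated data show — and do not show: they
validate the engine's logic, the pipeline's accounting, and that the
generator hits its own calibration targets. They cannot validate
distributional claims about real menus (menu-level correlation
structure, restaurant clustering, item-name semantics are all absent
from the generator), and flag-rate levels on synthetic data are not
estimates of real-sector flag rates.

## Problem sizes in the test suite

The suite exercises the engine-vs-oracle equivalence on 1000–1200
randomised items (with extra mass on exact boundary values), brute-force
tabulation checks at n = 5000, Monte-Carlo agreement of the closed-form
flag-rate oracle at n = 200 000 draws, and stochastic recovery of the
calibration (missingness/exemption fractions at n = 18 760; category
means and per-category flag rates at n = 10 000, judged at 3 standard
errors with 99 % binomial bands for the fractions). These sizes give
standard errors well inside the assertion bands while keeping the whole
suite in seconds.

## Known limitations

* Exemption is modelled purely as a subcategory-label lookup; the
  regulation's actual exemption *criteria* are richer and partly
  compositional.
* Free-text categorisation of item names into subcategories is out of
  scope; categories are taken as given columns.
* The children 1–4 y pathway ships without daily values (none are fixed
  by the sources the defaults encode).
* No inferential statistics across categories and no market-share
  weighting: the pipeline is descriptive by design.
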