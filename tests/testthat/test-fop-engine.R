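cfg <- fop_config()

test_that("band selection honours inclusive boundaries and age profiles", {
  expect_equal(select_band(c(1, 30), config = cfg), c("small", "small"))
  expect_equal(select_band(c(30.001, 100, 199.999), config = cfg),
               rep("standard", 3))
  expect_equal(select_band(c(200, 5000), config = cfg), c("large", "large"))
  # children 1-4 y main-dish cutoff is 170 g
  expect_equal(select_band(180, profile = "children_1to4", config = cfg),
               "large")
  expect_equal(select_band(169, profile = "children_1to4", config = cfg),
               "standard")
  expect_error(select_band(NA_real_, config = cfg), "exclude")
  expect_error(select_band(100, profile = "adults", config = cfg),
               "unknown age profile")
})

test_that("threshold lookups return the promulgated table literally", {
  expect_equal(threshold_for("sodium", c("small", "standard", "large"), cfg),
               c(230, 345, 690))
  expect_equal(threshold_for("total_sugars", c("small", "standard", "large"),
                             cfg), c(10, 15, 20))
  expect_equal(threshold_for("saturated_fat", c("small", "standard", "large"),
                             cfg), c(2, 3, 6))
  # the sugars large-band entry is stored, never derived as 30 % of the DV
  expect_equal(threshold_for("sugars", "large", cfg), 20)
  expect_error(threshold_for("protein", "small", cfg), "unknown nutrient")
  expect_error(threshold_for("sodium", "medium", cfg), "unknown band")
})

test_that("sugars_large_g option switches to the %DV-derived variant", {
  raw <- yaml::read_yaml(system.file("extdata", "fop_rules_canada2022.yaml",
                                     package = "menufop"))
  raw$options$sugars_large_g <- 30
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  alt <- fop_config(path)
  expect_equal(threshold_for("sugars", "large", alt), 30)
  expect_equal(threshold_for("sugars", "standard", alt), 15)
})

test_that("percent daily value is the unrounded ratio", {
  expect_equal(percent_dv(2300, "sodium", cfg), 100)
  expect_equal(percent_dv(0, "sugars", cfg), 0)
  expect_equal(percent_dv(690, "sodium", cfg), 30)
  expect_equal(percent_dv(5, "satfat", cfg), 25)
  expect_error(percent_dv(-1, "sodium", cfg), "non-negative")
})

test_that("exemption is a case-insensitive category-pair lookup", {
  expect_true(is_exempt("beverages", "water", cfg))
  expect_true(is_exempt("Beverages", "  Plain Milk ", cfg))
  expect_false(is_exempt("entrees", "poutine", cfg))
  expect_equal(is_exempt("beverages", c("water", "soft drinks"), cfg),
               c(TRUE, FALSE))
})

test_that("classification follows the flow chart with inclusive comparison", {
  # large-serving entree high in sodium and sat fat but not sugars
  res <- classify_item(list(major_category = "entrees",
                            sub_category = "poutine", serving_size = 250,
                            sodium_mg = 3373, sugars_g = 5, satfat_g = 43),
                       cfg)
  expect_equal(res$status, "assessed")
  expect_equal(res$band, "large")
  expect_equal(res$flags, c(sodium = TRUE, sugars = FALSE, satfat = TRUE))
  expect_equal(res$n_flags, 2L)
  expect_equal(res$thresholds,
               c(sodium_mg = 690, sugars_g = 20, satfat_g = 6))

  # meeting the threshold exactly flags the item ("meeting or exceeding")
  at_boundary <- classify_item(list(major_category = "sides",
                                    sub_category = "salads",
                                    serving_size = 100, sodium_mg = 345,
                                    sugars_g = 0, satfat_g = 0), cfg)
  expect_true(at_boundary$flags[["sodium"]])

  # one unit below the small-band threshold does not
  below <- classify_item(list(major_category = "sides",
                              sub_category = "salads", serving_size = 25,
                              sodium_mg = 229, sugars_g = 0, satfat_g = 0),
                         cfg)
  expect_equal(below$band, "small")
  expect_false(below$flags[["sodium"]])
})

test_that("exemption precedes the missing-serving check and zeroes flags", {
  # exempt item with huge nutrient values and no serving size: exempt,
  # never excluded, never flagged
  res <- classify_item(list(major_category = "beverages",
                            sub_category = "plain milk",
                            serving_size = NA_real_, sodium_mg = 9000,
                            sugars_g = 900, satfat_g = 900), cfg)
  expect_equal(res$status, "exempt")
  expect_equal(res$n_flags, 0L)
  expect_true(all(!res$flags))
  expect_true(is.na(res$band))
})

test_that("missing serving size excludes; missing nutrient flags FALSE with warning", {
  res <- classify_item(list(major_category = "entrees",
                            sub_category = "pizza", serving_size = NA_real_,
                            sodium_mg = 2000, sugars_g = 2, satfat_g = 2),
                       cfg)
  expect_equal(res$status, "excluded_missing_serving")
  expect_equal(res$n_flags, 0L)

  items <- make_items(1, serving = 250, sodium = NA_real_, sugars = 25,
                      satfat = 10)
  expect_warning(out <- classify_menu(items, cfg), "missing nutrient")
  expect_false(out$flag_sodium)
  expect_true(out$flag_sugars)
  expect_true(out$flag_satfat)
  expect_equal(out$n_flags, 2L)
})

test_that("config validation rejects malformed rule tables", {
  raw <- yaml::read_yaml(system.file("extdata", "fop_rules_canada2022.yaml",
                                     package = "menufop"))
  bad <- raw
  bad$thresholds$sodium_mg$large <- 100  # decreasing with band size
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path)
  expect_error(fop_config(path), "non-decreasing")

  bad2 <- raw
  bad2$bands$dv_percent$large <- 5
  yaml::write_yaml(bad2, path)
  expect_error(fop_config(path), "strictly increasing")
})
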