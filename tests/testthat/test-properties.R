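cfg <- fop_config()

test_that("classify_menu agrees with the literal flow-chart oracle", {
  items <- random_items(1000, seed = 11)
  got <- suppressWarnings(classify_menu(items, cfg))
  want <- oracle_classify_all(items, cfg)
  expect_equal(got$status, vapply(want, `[[`, "", "status"))
  expect_equal(got$band, vapply(want, `[[`, "", "band"))
  expect_equal(got$flag_sodium,
               vapply(want, function(w) w$flags[["sodium"]], TRUE))
  expect_equal(got$flag_sugars,
               vapply(want, function(w) w$flags[["sugars"]], TRUE))
  expect_equal(got$flag_satfat,
               vapply(want, function(w) w$flags[["satfat"]], TRUE))
  expect_equal(got$n_flags, vapply(want, `[[`, 1L, "n_flags"))
})

test_that("every positive serving size maps to exactly one band", {
  set.seed(22)
  s <- c(stats::runif(400, 1e-6, 500), 30, 200, 170,
         stats::rlnorm(100, 5, 2))
  band <- select_band(s, config = cfg)
  expect_true(all(band %in% c("small", "standard", "large")))
  in_small <- s <= 30
  in_large <- !in_small & s >= 200
  in_standard <- !in_small & !in_large
  expect_equal(band == "small", in_small)
  expect_equal(band == "large", in_large)
  expect_equal(band == "standard", in_standard)
})

test_that("flags are monotone in nutrient amount and thresholds in serving size", {
  set.seed(33)
  base <- random_items(200, seed = 33)
  base <- base[!is.na(base$serving_size), ]
  base$sodium_mg[is.na(base$sodium_mg)] <- 0
  res0 <- classify_menu(base, cfg)
  bumped <- base
  bumped$sodium_mg <- bumped$sodium_mg + stats::runif(nrow(base), 0, 500)
  bumped$sugars_g <- bumped$sugars_g + stats::runif(nrow(base), 0, 10)
  bumped$satfat_g <- bumped$satfat_g + stats::runif(nrow(base), 0, 5)
  res1 <- classify_menu(bumped, cfg)
  keep <- res0$status == "assessed"
  expect_true(all(res1$flag_sodium[keep] >= res0$flag_sodium[keep]))
  expect_true(all(res1$flag_sugars[keep] >= res0$flag_sugars[keep]))
  expect_true(all(res1$flag_satfat[keep] >= res0$flag_satfat[keep]))

  grown <- base
  grown$serving_size <- grown$serving_size * (1 + stats::runif(nrow(base)))
  res2 <- classify_menu(grown, cfg)
  keep2 <- keep & res2$status == "assessed"
  expect_true(all(res2$thr_sodium_mg[keep2] >= res0$thr_sodium_mg[keep2]))
  expect_true(all(res2$thr_sugars_g[keep2] >= res0$thr_sugars_g[keep2]))
  expect_true(all(res2$thr_satfat_g[keep2] >= res0$thr_satfat_g[keep2]))
})

test_that("exempt items carry zero flags whatever their nutrient levels", {
  set.seed(44)
  n <- 300
  items <- make_items(n, major = "beverages",
                      sub = sample(c("water", "plain milk", "alcohol"), n,
                                   replace = TRUE),
                      serving = sample(c(NA_real_, 10, 500), n,
                                       replace = TRUE),
                      sodium = stats::runif(n, 0, 10000),
                      sugars = stats::runif(n, 0, 500),
                      satfat = stats::runif(n, 0, 100))
  res <- classify_menu(items, cfg)
  expect_true(all(res$status == "exempt"))
  expect_true(all(res$n_flags == 0L))
  expect_true(all(!res$flag_sodium & !res$flag_sugars & !res$flag_satfat))
})

test_that("degenerate thresholds bound the flag count at 0 and 3", {
  items <- random_items(300, seed = 55)
  items$sodium_mg[is.na(items$sodium_mg)] <- 1
  items$sodium_mg <- items$sodium_mg + 1
  items$sugars_g <- items$sugars_g + 1
  items$satfat_g <- items$satfat_g + 1
  hi <- cfg
  for (k in c("sodium_mg", "sugars_g", "satfat_g")) {
    hi$thresholds[[k]] <- list(small = Inf, standard = Inf, large = Inf)
  }
  res_hi <- classify_menu(items, hi)
  expect_true(all(res_hi$n_flags[res_hi$status == "assessed"] == 0L))

  lo <- cfg
  for (k in c("sodium_mg", "sugars_g", "satfat_g")) {
    lo$thresholds[[k]] <- list(small = 1e-12, standard = 1e-12,
                               large = 1e-12)
  }
  res_lo <- classify_menu(items, lo)
  expect_true(all(res_lo$n_flags[res_lo$status == "assessed"] == 3L))
})

test_that("partition counts are conserved and order-invariant", {
  items <- random_items(2000, seed = 66)
  p <- suppressWarnings(partition_sample(items, cfg))$partition
  expect_equal(p$n_total,
               p$n_exempt + p$n_excluded_missing_serving + p$n_assessed)
  expect_equal(p$analytical_n, p$n_exempt + p$n_assessed)

  set.seed(67)
  shuffled <- items[sample.int(nrow(items)), ]
  res <- suppressWarnings(classify_menu(items, cfg))
  res_sh <- suppressWarnings(classify_menu(shuffled, cfg))
  expect_equal(summarize_symbols(shuffled, res_sh),
               summarize_symbols(items, res))
  expect_equal(summarize_nutrient_flags(shuffled, res_sh),
               summarize_nutrient_flags(items, res))
})

test_that("tabulations equal a brute-force per-item tally", {
  items <- random_items(5000, seed = 77)
  res <- suppressWarnings(classify_menu(items, cfg))
  sym <- summarize_symbols(items, res)
  nut <- summarize_nutrient_flags(items, res)
  oracle <- oracle_classify_all(items, cfg)
  keep <- vapply(oracle, `[[`, "", "status") != "excluded_missing_serving"
  nf <- vapply(oracle, `[[`, 1L, "n_flags")[keep]
  ov <- sym[sym$category == "overall", ]
  expect_equal(ov$analytical_n, sum(keep))
  expect_equal(c(ov$n0, ov$n1, ov$n2, ov$n3),
               as.vector(tabulate(nf + 1L, 4L)))
  flags <- t(vapply(oracle, function(w) w$flags, logical(3)))[keep, ]
  nov <- nut[nut$category == "overall", ]
  expect_equal(c(nov$n_sodium, nov$n_sugars, nov$n_satfat),
               unname(colSums(flags)))
  # conservation: per-nutrient totals = n1 + 2 n2 + 3 n3, every category row
  for (i in seq_len(nrow(sym))) {
    s <- sym[i, ]
    n_row <- nut[nut$category == s$category, ]
    expect_equal(n_row$n_sodium + n_row$n_sugars + n_row$n_satfat,
                 s$n1 + 2 * s$n2 + 3 * s$n3)
  }
  # category rows sum to the overall row
  by_cat <- sym[sym$category != "overall", ]
  expect_equal(sum(by_cat$analytical_n), ov$analytical_n)
  expect_equal(sum(by_cat$n_any), ov$n_any)
})

test_that("printed percentages recompute from their own counts within rounding", {
  items <- random_items(3000, seed = 88)
  res <- suppressWarnings(classify_menu(items, cfg))
  sym <- summarize_symbols(items, res)
  for (i in seq_len(nrow(sym))) {
    s <- sym[i, ]
    expect_lte(abs(s$pct_any - 100 * s$n_any / s$analytical_n), 0.5)
    if (s$n_any > 0) {
      expect_lte(abs(s$pct1_of_displayers - 100 * s$n1 / s$n_any), 0.5)
    }
  }
})
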