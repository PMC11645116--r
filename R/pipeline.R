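#' Partition a menu sample into exempt / excluded / assessed
#'
#' Runs the classification engine over the whole dataset and tallies the
#' flow-chart partition: items exempt by category, items excluded for a
#' missing serving size, and items assessed against the thresholds. The
#' analytical sample is exempt + assessed — exempt items stay in the
#' denominators as "no FOP symbol"; excluded items drop out entirely.
#'
#' @param items menu tibble (see [read_menu_table()], [generate_menu()]).
#' @param config an [fop_config()] object.
#' @param profile age profile passed to [classify_menu()].
#' @return list with `partition`, a one-row tibble of counts
#'   (`n_total`, `n_exempt`, `n_excluded_missing_serving`, `n_assessed`,
#'   `analytical_n`) and percentages at one decimal
#'   (`pct_exempt_of_total`, `pct_missing_of_total`,
#'   `pct_assessed_of_remaining` — the last on the total net of
#'   exemptions), and `classified`, the per-item tibble from
#'   [classify_menu()].
#' @export
partition_sample <- function(items, config = fop_config(),
                             profile = "adults_children_over4") {
  classified <- classify_menu(items, config, profile)
  n_total <- nrow(classified)
  n_exempt <- sum(classified$status == "exempt")
  n_excl <- sum(classified$status == "excluded_missing_serving")
  n_assessed <- sum(classified$status == "assessed")
  remaining <- n_total - n_exempt
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  list(
    partition = tibble::tibble(
      n_total = n_total,
      n_exempt = n_exempt,
      n_excluded_missing_serving = n_excl,
      n_assessed = n_assessed,
      analytical_n = n_exempt + n_assessed,
      pct_exempt_of_total = pct(n_exempt, n_total),
      pct_missing_of_total = pct(n_excl, n_total),
      pct_assessed_of_remaining = pct(n_assessed, remaining)
    ),
    classified = classified
  )
}

#' Symbol-count table from raw counts
#'
#' Builds one row of the symbol tabulation from counts of items with
#' 0, 1, 2 and 3 "high-in" flags. Percentages are reported on two
#' denominators: the analytical sample (`pct_any`, `pct0`..`pct3`) and,
#' for the 1/2/3-nutrient split, the symbol-displaying items
#' (`pct1_of_displayers` etc.). All percentages are rounded half-up to
#' integers.
#'
#' @param n0,n1,n2,n3 item counts by number of flags.
#' @param category row label (default `"overall"`).
#' @return one-row tibble.
#' @examples
#' symbol_table_from_counts(n0 = 3066, n1 = 4400, n2 = 5491, n3 = 326)
#' @export
symbol_table_from_counts <- function(n0, n1, n2, n3, category = "overall") {
  n <- n0 + n1 + n2 + n3
  n_any <- n1 + n2 + n3
  ipct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  tibble::tibble(
    category = category,
    analytical_n = n,
    n0 = n0, n1 = n1, n2 = n2, n3 = n3,
    n_any = n_any,
    pct_any = ipct(n_any, n),
    pct0 = ipct(n0, n), pct1 = ipct(n1, n),
    pct2 = ipct(n2, n), pct3 = ipct(n3, n),
    pct1_of_displayers = ipct(n1, n_any),
    pct2_of_displayers = ipct(n2, n_any),
    pct3_of_displayers = ipct(n3, n_any)
  )
}

#' Tabulate FOP symbol outcomes by category
#'
#' Counts and percentages of items displaying a symbol for 0, 1, 2 or 3
#' nutrients, overall and per major category, over the analytical sample
#' (exempt items count as 0 flags; excluded items are omitted).
#'
#' @param items menu tibble; supplies `major_category` per item.
#' @param results classification tibble from [classify_menu()].
#' @return tibble with an `"overall"` row followed by one row per major
#'   category present; columns as in [symbol_table_from_counts()].
#'   Empty input yields a zero-row tibble.
#' @export
summarize_symbols <- function(items, results) {
  dat <- analytical_join(items, results)
  if (nrow(dat) == 0) return(symbol_table_from_counts(0, 0, 0, 0)[0, ])
  one <- function(d, label) {
    k <- tabulate(d$n_flags + 1L, nbins = 4L)
    symbol_table_from_counts(k[1], k[2], k[3], k[4], category = label)
  }
  dplyr::bind_rows(
    one(dat, "overall"),
    dat |>
      dplyr::group_by(.data$major_category) |>
      dplyr::group_map(~ one(.x, .y$major_category)) |>
      dplyr::bind_rows()
  )
}

#' Nutrient-flag table from raw counts
#'
#' @param n_sodium,n_sugars,n_satfat counts of items flagged "high-in"
#'   each nutrient.
#' @param analytical_n denominator (analytical sample size).
#' @param category row label.
#' @return one-row tibble with counts and half-up integer percentages on
#'   the analytical sample.
#' @examples
#' nutrient_table_from_counts(6972, 3135, 6253, analytical_n = 13283)
#' @export
nutrient_table_from_counts <- function(n_sodium, n_sugars, n_satfat,
                                       analytical_n, category = "overall") {
  ipct <- function(num) {
    if (analytical_n == 0) NA_real_ else round_half_up(100 * num / analytical_n)
  }
  tibble::tibble(
    category = category,
    analytical_n = analytical_n,
    n_sodium = n_sodium, pct_sodium = ipct(n_sodium),
    n_sugars = n_sugars, pct_sugars = ipct(n_sugars),
    n_satfat = n_satfat, pct_satfat = ipct(n_satfat)
  )
}

#' Tabulate per-nutrient "high-in" flags by category
#'
#' Counts and percentages of analytical-sample items flagged "high-in"
#' sodium, total sugars and saturated fat, overall and per major
#' category.
#'
#' @inheritParams summarize_symbols
#' @return tibble shaped as [nutrient_table_from_counts()] rows.
#' @export
summarize_nutrient_flags <- function(items, results) {
  dat <- analytical_join(items, results)
  if (nrow(dat) == 0) return(nutrient_table_from_counts(0, 0, 0, 0)[0, ])
  one <- function(d, label) {
    nutrient_table_from_counts(sum(d$flag_sodium), sum(d$flag_sugars),
                               sum(d$flag_satfat), nrow(d), category = label)
  }
  dplyr::bind_rows(
    one(dat, "overall"),
    dat |>
      dplyr::group_by(.data$major_category) |>
      dplyr::group_map(~ one(.x, .y$major_category)) |>
      dplyr::bind_rows()
  )
}

analytical_join <- function(items, results) {
  stopifnot(all(c("item_id", "major_category") %in% names(items)))
  dplyr::inner_join(items[, c("item_id", "major_category")], results,
                    by = "item_id") |>
    dplyr::filter(.data$status != "excluded_missing_serving")
}

#' Descriptive statistics of energy and nutrients-of-concern
#'
#' Mean and median per serving, with 95 % confidence intervals, by major
#' or submenu category. Mean CIs use the t distribution; median CIs use
#' a seeded bootstrap percentile interval. Missing values are dropped
#' per nutrient; groups with fewer than two observations report point
#' estimates with undefined (`NA`) intervals.
#'
#' @param items menu tibble.
#' @param group_by `"major"` or `"sub"` (sub groups are labelled
#'   `major/sub`).
#' @param conf confidence level (default 0.95).
#' @param n_boot bootstrap resamples for the median CI (default 1000).
#' @param seed integer seed for the bootstrap (recorded in reports).
#' @return long tibble: `group`, `nutrient` (calories_kcal, sodium_mg,
#'   sugars_g, satfat_g), `n`, `mean`, `mean_lo`, `mean_hi`, `median`,
#'   `median_lo`, `median_hi`.
#' @export
descriptive_stats <- function(items, group_by = c("major", "sub"),
                              conf = 0.95, n_boot = 1000L, seed = 1L) {
  group_by <- match.arg(group_by)
  grp <- if (group_by == "major") {
    items$major_category
  } else {
    paste(items$major_category, items$sub_category, sep = "/")
  }
  nut_cols <- c("calories_kcal", "sodium_mg", "sugars_g", "satfat_g")
  nut_cols <- intersect(nut_cols, names(items))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  alpha <- 1 - conf
  rows <- list()
  for (g in sort(unique(grp))) {
    for (col in nut_cols) {
      x <- items[[col]][grp == g]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0) next
      m <- mean(x)
      med <- stats::median(x)
      if (n >= 2) {
        half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(x) / sqrt(n)
        boot_meds <- vapply(seq_len(n_boot), function(i) {
          stats::median(x[sample.int(n, n, replace = TRUE)])
        }, numeric(1))
        med_ci <- stats::quantile(boot_meds, c(alpha / 2, 1 - alpha / 2),
                                  names = FALSE, type = 7)
        mean_ci <- c(m - half, m + half)
      } else {
        mean_ci <- c(NA_real_, NA_real_)
        med_ci <- c(NA_real_, NA_real_)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, nutrient = col, n = n,
        mean = m, mean_lo = mean_ci[1], mean_hi = mean_ci[2],
        median = med, median_lo = med_ci[1], median_hi = med_ci[2]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(group = character(), nutrient = character(),
                          n = integer(), mean = numeric(), mean_lo = numeric(),
                          mean_hi = numeric(), median = numeric(),
                          median_lo = numeric(), median_hi = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Sensitivity analysis for items missing serving sizes
#'
#' Items excluded from the main analysis for lack of a numeric serving
#' size are re-classified under an *imposed* %DV band per major
#' category — by default 15 % DV (standard band) for desserts and sides,
#' whose category-mean servings fall below the main-dish cutoff, and
#' 30 % DV (large band) for beverages, entrées and starters.
#'
#' @param items menu tibble containing only items with missing serving
#'   size; an item with a serving present is an error (it belongs in the
#'   main analysis).
#' @param dv_map named numeric vector mapping every major category to an
#'   imposed dv_percent (10, 15 or 30).
#' @param config an [fop_config()] object.
#' @return list with `results` (per-item tibble shaped like
#'   [classify_menu()] output, status `"assessed"`), `symbols`
#'   ([summarize_symbols()] table) and `nutrients`
#'   ([summarize_nutrient_flags()] table). Empty input yields empty
#'   tables.
#' @export
sensitivity_missing_serving <- function(items,
                                        dv_map = c(beverages = 30,
                                                   desserts = 15,
                                                   entrees = 30,
                                                   sides = 15,
                                                   starters = 30),
                                        config = fop_config()) {
  if (any(!is.na(items$serving_size))) {
    stop("item(s) with a serving size present: these belong in the main ",
         "analysis, not the sensitivity analysis", call. = FALSE)
  }
  missing_major <- setdiff(unique(items$major_category), names(dv_map))
  if (length(missing_major) > 0) {
    stop("dv_map does not cover major category: ",
         paste(missing_major, collapse = ", "), call. = FALSE)
  }
  dvp <- unlist(config$bands$dv_percent[.band_levels])
  band_of_pct <- stats::setNames(.band_levels, as.character(dvp))
  bad_pct <- setdiff(as.character(dv_map), names(band_of_pct))
  if (length(bad_pct) > 0) {
    stop("dv_map percent(s) with no matching band: ",
         paste(bad_pct, collapse = ", "), call. = FALSE)
  }

  n <- nrow(items)
  if (n == 0) {
    empty_sym <- symbol_table_from_counts(0, 0, 0, 0)[0, ]
    empty_nut <- nutrient_table_from_counts(0, 0, 0, 0)[0, ]
    return(list(results = classify_menu(items[0, , drop = FALSE], config),
                symbols = empty_sym, nutrients = empty_nut))
  }
  band <- unname(band_of_pct[as.character(dv_map[items$major_category])])
  flags <- matrix(FALSE, n, 3, dimnames = list(NULL, .nutrients))
  thr <- matrix(NA_real_, n, 3, dimnames = list(NULL, .nutrients))
  for (nut in .nutrients) {
    col <- .nutrient_cols[[nut]]
    amount <- if (col %in% names(items)) items[[col]] else rep(NA_real_, n)
    thr[, nut] <- threshold_for(nut, band, config)
    hit <- amount >= thr[, nut]
    hit[is.na(hit)] <- FALSE
    flags[, nut] <- hit
  }
  results <- tibble::tibble(
    item_id = items$item_id,
    status = "assessed",
    band = band,
    flag_sodium = flags[, "sodium"],
    flag_sugars = flags[, "sugars"],
    flag_satfat = flags[, "satfat"],
    n_flags = as.integer(rowSums(flags)),
    thr_sodium_mg = thr[, "sodium"],
    thr_sugars_g = thr[, "sugars"],
    thr_satfat_g = thr[, "satfat"]
  )
  list(results = results,
       symbols = summarize_symbols(items, results),
       nutrients = summarize_nutrient_flags(items, results))
}

#' Write the analysis tables and a markdown report
#'
#' Writes each supplied table as CSV plus a `report.md` summarising the
#' partition, the symbol outcomes and the per-nutrient flags in the
#' order of the analysis. Output is deterministic: identical input
#' produces byte-identical files.
#'
#' @param tables named list; recognised elements `partition`, `symbols`,
#'   `nutrients`, `stats`, `sensitivity_symbols`,
#'   `sensitivity_nutrients` (any subset; each a tibble from the
#'   corresponding summarising function).
#' @param dir output directory (created if absent).
#' @param seed optional integer recorded in the report header (the
#'   bootstrap seed used for median CIs, if any).
#' @return invisibly, the path of the markdown report.
#' @export
render_report <- function(tables, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  lines <- c("# Front-of-package 'high-in' classification report", "")
  if (!is.null(seed)) {
    lines <- c(lines, paste0("Bootstrap seed: ", seed), "")
  }
  fmt <- function(x) format(x, big.mark = " ", trim = TRUE, scientific = FALSE)
  p <- tables$partition
  if (!is.null(p) && nrow(p) == 1) {
    lines <- c(lines, "## Sample partition", "",
      paste0("- Total items: ", fmt(p$n_total)),
      paste0("- Exempt by category: ", fmt(p$n_exempt), " (",
             p$pct_exempt_of_total, " % of total)"),
      paste0("- Excluded, missing serving size: ",
             fmt(p$n_excluded_missing_serving), " (",
             p$pct_missing_of_total, " % of total)"),
      paste0("- Assessed: ", fmt(p$n_assessed), " (",
             p$pct_assessed_of_remaining, " % of items net of exemptions)"),
      paste0("- Analytical sample (assessed + exempt): ",
             fmt(p$analytical_n)),
      "")
  }
  s <- tables$symbols
  if (!is.null(s) && nrow(s) > 0) {
    ov <- s[s$category == "overall", ]
    if (nrow(ov) == 1) {
      lines <- c(lines, "## Symbol outcomes", "",
        paste0("Overall, ", ov$pct_any, " % of menu items (n ", fmt(ov$n_any),
               ") would display a 'high-in' FOP symbol, while ", ov$pct0,
               " % (n ", fmt(ov$n0), ") would not."),
        paste0("Among items displaying a symbol, ", ov$pct1_of_displayers,
               " % would indicate one 'high-in' nutrient, ",
               ov$pct2_of_displayers, " % two and ", ov$pct3_of_displayers,
               " % all three nutrients-of-concern."),
        "")
    }
    by_cat <- s[s$category != "overall", ]
    if (nrow(by_cat) > 0) {
      lines <- c(lines, "Per category (% displaying any symbol):",
        paste0("- ", by_cat$category, ": ", by_cat$pct_any, " % (n ",
               fmt(by_cat$n_any), " of ", fmt(by_cat$analytical_n), ")"),
        "")
    }
  }
  nf <- tables$nutrients
  if (!is.null(nf) && nrow(nf) > 0) {
    ov <- nf[nf$category == "overall", ]
    if (nrow(ov) == 1) {
      lines <- c(lines, "## 'High-in' flags by nutrient", "",
        paste0("Overall, ", ov$pct_sodium, " % (n ", fmt(ov$n_sodium),
               ") of analytical-sample items would indicate 'high-in' ",
               "sodium, ", ov$pct_sugars, " % (n ", fmt(ov$n_sugars),
               ") 'high-in' total sugars and ", ov$pct_satfat, " % (n ",
               fmt(ov$n_satfat), ") 'high-in' saturated fat."),
        "")
    }
  }
  if (!is.null(tables$stats)) {
    lines <- c(lines, "## Descriptive statistics", "",
      "Mean and median per serving with 95 % CIs: see stats.csv.", "")
  }
  if (!is.null(tables$sensitivity_symbols)) {
    lines <- c(lines, "## Sensitivity analysis (items missing serving size)",
      "",
      "Imposed-band classification: see sensitivity_symbols.csv and ",
      "sensitivity_nutrients.csv.", "")
  }
  report_path <- file.path(dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}

#' Stacked-bar plot of symbol outcomes by category
#'
#' @param symbols table from [summarize_symbols()].
#' @return a ggplot object: percentage of analytical-sample items with
#'   0/1/2/3 flags per category.
#' @export
plot_symbol_counts <- function(symbols) {
  long <- symbols |>
    dplyr::select("category", "pct0", "pct1", "pct2", "pct3") |>
    tidyr::pivot_longer(-"category", names_to = "flags",
                        values_to = "percent") |>
    dplyr::mutate(flags = factor(.data$flags,
                                 levels = c("pct3", "pct2", "pct1", "pct0"),
                                 labels = c("3 nutrients", "2 nutrients",
                                            "1 nutrient", "no symbol")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$percent,
                                     fill = .data$flags)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of analytical sample",
                  fill = "FOP symbol") +
    ggplot2::theme_minimal()
}
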