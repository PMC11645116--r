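#' Select the serving-size band for an item
#'
#' Maps a stated serving size onto the regulation's three threshold bands:
#' `small` for servings of 30 g or less (10 % DV), `large` for servings at
#' or above the profile's main-dish cutoff (200 g for adults and children
#' over 4 y, 170 g for children 1-4 y; 30 % DV), and `standard` otherwise
#' (15 % DV). Both boundaries are inclusive toward their band. Millilitre
#' servings are treated as numerically equivalent to grams (density 1).
#'
#' @param serving_g numeric vector of serving sizes in g (or mL).
#' @param profile `"adults_children_over4"` (default) or `"children_1to4"`.
#' @param config an [fop_config()] object.
#' @return character vector of band names (`"small"`, `"standard"`,
#'   `"large"`). Missing or non-positive servings are an error: such items
#'   must be excluded, not banded.
#' @examples
#' select_band(c(30, 100, 200))
#' select_band(180, profile = "children_1to4")
#' @export
select_band <- function(serving_g, profile = "adults_children_over4",
                        config = fop_config()) {
  prof <- config$profiles[[profile]]
  if (is.null(prof)) {
    stop("unknown age profile: ", profile, call. = FALSE)
  }
  if (any(is.na(serving_g)) || any(serving_g <= 0)) {
    stop("serving size absent or non-positive: exclude the item rather ",
         "than selecting a band", call. = FALSE)
  }
  cutoff <- prof$main_dish_cutoff_g
  dplyr::case_when(
    serving_g <= config$bands$small_max_g ~ "small",
    serving_g >= cutoff ~ "large",
    TRUE ~ "standard"
  )
}

#' Look up the absolute threshold for a nutrient and band
#'
#' Returns the literal table entry (mg for sodium, g otherwise); values
#' are never recomputed from %DV at query time, so the promulgated 20 g
#' sugars large-band threshold is returned as-is.
#'
#' @param nutrient one of `"sodium"`, `"sugars"` (total sugars),
#'   `"satfat"` (saturated fat); the aliases `"total_sugars"` and
#'   `"saturated_fat"` are accepted.
#' @param band band name vector as returned by [select_band()].
#' @param config an [fop_config()] object.
#' @return numeric vector of threshold amounts.
#' @examples
#' threshold_for("sodium", "standard")  # 345 mg
#' threshold_for("satfat", "large")     # 6 g
#' @export
threshold_for <- function(nutrient, band, config = fop_config()) {
  key <- normalize_nutrient(nutrient)
  if (!all(band %in% .band_levels)) {
    stop("unknown band: ", paste(setdiff(band, .band_levels), collapse = ", "),
         call. = FALSE)
  }
  tab <- unlist(config$thresholds[[.nutrient_cols[[key]]]][.band_levels])
  unname(tab[band])
}

normalize_nutrient <- function(nutrient) {
  stopifnot(length(nutrient) == 1)
  aliases <- c(sodium = "sodium", sugars = "sugars", total_sugars = "sugars",
               satfat = "satfat", saturated_fat = "satfat")
  key <- unname(aliases[tolower(nutrient)])
  if (is.na(key)) {
    stop("unknown nutrient: ", nutrient,
         " (expected sodium, sugars/total_sugars, satfat/saturated_fat)",
         call. = FALSE)
  }
  key
}

#' Express a nutrient amount as percent daily value
#'
#' @param amount nutrient amount per serving (mg for sodium, g otherwise);
#'   must be non-negative.
#' @param nutrient nutrient name, as in [threshold_for()].
#' @param config an [fop_config()] object supplying the daily values.
#' @return `100 * amount / DV`, unrounded.
#' @examples
#' percent_dv(690, "sodium")  # 30
#' @export
percent_dv <- function(amount, nutrient, config = fop_config()) {
  if (any(amount < 0, na.rm = TRUE)) {
    stop("nutrient amount must be non-negative", call. = FALSE)
  }
  key <- normalize_nutrient(nutrient)
  100 * amount / config$daily_values[[.nutrient_cols[[key]]]]
}

#' Test whether a menu item's category is exempt from assessment
#'
#' Exemption is a property of the (major, sub) category pair alone and is
#' evaluated before the serving-size check: an exempt item needs no
#' serving size and never displays a symbol, regardless of its nutrient
#' content. Matching is case-insensitive and whitespace-trimmed.
#'
#' @param major,sub character vectors of major and sub category labels
#'   (recycled to common length).
#' @param config an [fop_config()] object carrying the exempt
#'   subcategory list.
#' @return logical vector.
#' @examples
#' is_exempt("beverages", c("water", "juices/smoothies"))
#' @export
is_exempt <- function(major, sub, config = fop_config()) {
  canon <- function(x) tolower(trimws(as.character(x)))
  keys <- vapply(config$exempt_subcategories,
                 function(e) paste(canon(e$major), canon(e$sub), sep = "\r"),
                 character(1))
  paste(canon(major), canon(sub), sep = "\r") %in% keys
}

#' Classify a whole menu table against the FOP rules
#'
#' Applies the regulation to each row of a validated menu table. Each
#' item is (1) tested for category exemption; (2) if not exempt and its
#' serving size is missing, excluded; (3) otherwise assessed: the
#' serving-size band is selected and, per nutrient, the item is flagged
#' "high-in" when its amount **meets or exceeds** the band's threshold
#' (inclusive comparison). Nutrient amounts are compared unrounded.
#'
#' A missing nutrient value on an assessed item yields `FALSE` for that
#' nutrient's flag (absence of evidence that the threshold is met) and a
#' single summary warning.
#'
#' @param items a menu tibble as produced by [read_menu_table()] or
#'   [generate_menu()]: columns `item_id`, `major_category`,
#'   `sub_category`, `serving_size`, `serving_unit`, `sodium_mg`,
#'   `sugars_g`, `satfat_g` (plus any others, ignored).
#' @param config an [fop_config()] object.
#' @param profile age profile passed to [select_band()].
#' @return a tibble, one row per item, with `item_id`, `status`
#'   (`"exempt"`, `"excluded_missing_serving"` or `"assessed"`), `band`
#'   (`NA` unless assessed), logical `flag_sodium`, `flag_sugars`,
#'   `flag_satfat`, integer `n_flags`, and the applied thresholds
#'   `thr_sodium_mg`, `thr_sugars_g`, `thr_satfat_g` (`NA` unless
#'   assessed).
#' @seealso [classify_item()] for a single item.
#' @examples
#' items <- generate_menu(calibrated_generator_config(n_items = 50), seed = 1)
#' classify_menu(items)
#' @export
classify_menu <- function(items, config = fop_config(),
                          profile = "adults_children_over4") {
  stopifnot(is.data.frame(items))
  need <- c("item_id", "major_category", "sub_category", "serving_size")
  miss <- setdiff(need, names(items))
  if (length(miss) > 0) {
    stop("menu table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(items)
  exempt <- is_exempt(items$major_category, items$sub_category, config)
  serving <- items$serving_size
  excluded <- !exempt & (is.na(serving) | serving <= 0)
  assessed <- !exempt & !excluded

  status <- rep("assessed", n)
  status[exempt] <- "exempt"
  status[excluded] <- "excluded_missing_serving"

  band <- rep(NA_character_, n)
  if (any(assessed)) {
    band[assessed] <- select_band(serving[assessed], profile, config)
  }

  flags <- matrix(FALSE, n, 3, dimnames = list(NULL, .nutrients))
  thr <- matrix(NA_real_, n, 3, dimnames = list(NULL, .nutrients))
  n_missing_nutrient <- 0L
  for (nut in .nutrients) {
    col <- .nutrient_cols[[nut]]
    amount <- if (col %in% names(items)) items[[col]] else rep(NA_real_, n)
    if (any(assessed)) {
      thr[assessed, nut] <- threshold_for(nut, band[assessed], config)
      hit <- amount[assessed] >= thr[assessed, nut]
      na_hit <- is.na(hit)
      n_missing_nutrient <- n_missing_nutrient + sum(na_hit)
      hit[na_hit] <- FALSE
      flags[assessed, nut] <- hit
    }
  }
  if (n_missing_nutrient > 0) {
    warning(n_missing_nutrient, " missing nutrient value(s) on assessed ",
            "items treated as below threshold (flag = FALSE)", call. = FALSE)
  }

  tibble::tibble(
    item_id = items$item_id,
    status = status,
    band = band,
    flag_sodium = flags[, "sodium"],
    flag_sugars = flags[, "sugars"],
    flag_satfat = flags[, "satfat"],
    n_flags = as.integer(rowSums(flags)),
    thr_sodium_mg = thr[, "sodium"],
    thr_sugars_g = thr[, "sugars"],
    thr_satfat_g = thr[, "satfat"]
  )
}

#' Classify a single menu item
#'
#' Convenience wrapper around [classify_menu()] for one item given as a
#' named list or one-row data frame.
#'
#' @param item named list or one-row data frame with the fields used by
#'   [classify_menu()].
#' @inheritParams classify_menu
#' @return a named list: `status`, `band`, `flags` (named logical vector
#'   over sodium/sugars/satfat), `n_flags`, `thresholds` (named numeric).
#' @examples
#' classify_item(list(major_category = "entrees", sub_category = "poutine",
#'                    serving_size = 250, sodium_mg = 3373,
#'                    sugars_g = 5, satfat_g = 43))
#' @export
classify_item <- function(item, config = fop_config(),
                          profile = "adults_children_over4") {
  row <- tibble::tibble(
    item_id = item$item_id %||% "item",
    major_category = item$major_category,
    sub_category = item$sub_category,
    serving_size = item$serving_size %||% NA_real_,
    serving_unit = item$serving_unit %||% "g",
    sodium_mg = item$sodium_mg %||% NA_real_,
    sugars_g = item$sugars_g %||% NA_real_,
    satfat_g = item$satfat_g %||% NA_real_
  )
  res <- classify_menu(row, config, profile)
  list(
    status = res$status,
    band = res$band,
    flags = c(sodium = unname(res$flag_sodium),
              sugars = unname(res$flag_sugars),
              satfat = unname(res$flag_satfat)),
    n_flags = res$n_flags,
    thresholds = c(sodium_mg = unname(res$thr_sodium_mg),
                   sugars_g = unname(res$thr_sugars_g),
                   satfat_g = unname(res$thr_satfat_g))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
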