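#' Default menu table schema
#'
#' Loads the shipped column mapping and subcategory vocabulary. The
#' mapping translates the canonical column names used throughout the
#' package to the column names present in an input file; the vocabulary
#' lists the admissible subcategory labels per major category.
#'
#' @param path path to a YAML schema file; `NULL` loads the shipped one.
#' @return a list with elements `columns` (named character mapping) and
#'   `vocabulary` (named list of character vectors, one per major
#'   category).
#' @export
default_menu_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "menu_schema.yaml",
                        package = "menufop", mustWork = TRUE)
  }
  schema <- yaml::read_yaml(path)
  schema$columns <- unlist(schema$columns)
  schema
}

#' Read a menu-item table from delimited text
#'
#' Reads a CSV of menu items (one row per item), maps columns via the
#' schema, and validates field-level constraints. Blank or unparseable
#' serving sizes become `NA` — never 0 — so the item is later excluded
#' rather than banded. Unparseable or negative nutrient/serving values
#' are recorded as validation problems (row kept, offending value set to
#' `NA`); retrieve them with [menu_validation()]. Major categories
#' outside the five-level vocabulary and subcategories outside their
#' major's vocabulary are likewise recorded.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema a schema list as from [default_menu_schema()], or a path
#'   to a YAML schema file; `NULL` uses the shipped schema.
#' @return a tibble with canonical columns `item_id`, `restaurant`,
#'   `item_name`, `major_category`, `sub_category`, `serving_size`,
#'   `serving_unit`, `calories_kcal`, `sodium_mg`, `sugars_g`,
#'   `satfat_g`, carrying a `validation` attribute (tibble of
#'   row/column/value/message).
#' @section Errors: a missing file, a missing mapped column, or a
#'   duplicated `item_id` is a hard error naming the offender.
#' @export
read_menu_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("menu file not found: ", path, call. = FALSE)
  }
  if (is.null(schema)) schema <- default_menu_schema()
  if (is.character(schema)) schema <- default_menu_schema(schema)
  mapping <- schema$columns

  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  miss <- setdiff(unname(mapping), names(raw))
  if (length(miss) > 0) {
    stop("input file lacks mapped column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(stats::setNames(raw[unname(mapping)], names(mapping)))

  problems <- list()
  note <- function(row, column, value, message) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      row = row, column = column, value = as.character(value),
      message = message)
  }

  # numeric fields: blank -> NA silently (missing), junk/negative -> problem
  numeric_cols <- c("serving_size", "calories_kcal", "sodium_mg",
                    "sugars_g", "satfat_g")
  for (col in numeric_cols) {
    chr <- trimws(out[[col]])
    chr[chr == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(chr))
    bad_parse <- which(!is.na(chr) & is.na(val))
    for (i in bad_parse) note(i, col, chr[i], "not a number")
    neg <- which(!is.na(val) & val < 0)
    for (i in neg) note(i, col, val[i], "negative value")
    val[neg] <- NA_real_
    if (col == "serving_size") {
      zero <- which(!is.na(val) & val == 0)
      for (i in zero) note(i, col, 0, "serving size must be > 0")
      val[zero] <- NA_real_
    }
    out[[col]] <- val
  }

  out$serving_unit <- tolower(trimws(out$serving_unit))
  out$serving_unit[out$serving_unit == ""] <- NA_character_
  bad_unit <- which(!is.na(out$serving_unit) &
                      !out$serving_unit %in% c("g", "ml"))
  for (i in bad_unit) note(i, "serving_unit", out$serving_unit[i],
                           "unit must be g or mL")

  dup <- out$item_id[duplicated(out$item_id)]
  if (length(dup) > 0) {
    stop("duplicate item_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  out$major_category <- tolower(trimws(out$major_category))
  out$sub_category <- tolower(trimws(out$sub_category))
  bad_major <- which(!out$major_category %in% .major_levels)
  for (i in bad_major) note(i, "major_category", out$major_category[i],
                            "not one of the five major categories")
  vocab <- schema$vocabulary
  if (!is.null(vocab)) {
    ok_major <- setdiff(seq_len(nrow(out)), bad_major)
    for (i in ok_major) {
      allowed <- tolower(vocab[[out$major_category[i]]])
      if (!out$sub_category[i] %in% allowed) {
        note(i, "sub_category", out$sub_category[i],
             "not in the vocabulary for its major category")
      }
    }
  }

  attr(out, "validation") <- if (length(problems) > 0) {
    dplyr::bind_rows(problems)
  } else {
    tibble::tibble(row = integer(), column = character(),
                   value = character(), message = character())
  }
  out
}

#' Validation problems recorded while reading a menu table
#'
#' @param items a tibble returned by [read_menu_table()].
#' @return tibble of `row`, `column`, `value`, `message` (zero rows when
#'   the file was clean).
#' @export
menu_validation <- function(items) {
  v <- attr(items, "validation")
  if (is.null(v)) {
    tibble::tibble(row = integer(), column = character(),
                   value = character(), message = character())
  } else {
    v
  }
}

#' Write a classified menu table
#'
#' Writes the original item columns plus the classification outcome:
#' `status`, the per-nutrient 0/1 flags, `n_flags`, the band applied and
#' the thresholds applied. Exempt rows carry explicit `0` flags (assessed
#' nothing, displays nothing); excluded rows carry *empty* flag cells —
#' "not assessed" is distinct from "assessed and not high-in". The file
#' round-trips losslessly through [read_classified_table()].
#'
#' @param items menu tibble (see [read_menu_table()]).
#' @param results classification tibble from [classify_menu()], matching
#'   `items` one-to-one by `item_id` (any order).
#' @param path output CSV path.
#' @return invisibly, the written tibble.
#' @export
write_classified_table <- function(items, results, path) {
  if (nrow(items) != nrow(results)) {
    stop("items (", nrow(items), ") and results (", nrow(results),
         ") differ in length", call. = FALSE)
  }
  unknown <- setdiff(results$item_id, items$item_id)
  if (length(unknown) > 0 || anyDuplicated(results$item_id) > 0) {
    stop("results do not align one-to-one with items by item_id",
         if (length(unknown) > 0)
           paste0(": unknown id ", unknown[1]), call. = FALSE)
  }
  res <- results[match(items$item_id, results$item_id), ]
  excluded <- res$status == "excluded_missing_serving"
  fmt_flag <- function(f) {
    out <- as.integer(f)
    out[excluded] <- NA_integer_
    out
  }
  out <- dplyr::bind_cols(
    items,
    tibble::tibble(
      status = res$status,
      flag_sodium = fmt_flag(res$flag_sodium),
      flag_sugars = fmt_flag(res$flag_sugars),
      flag_satfat = fmt_flag(res$flag_satfat),
      n_flags = ifelse(excluded, NA_integer_, res$n_flags),
      band = res$band,
      thr_sodium_mg = res$thr_sodium_mg,
      thr_sugars_g = res$thr_sugars_g,
      thr_satfat_g = res$thr_satfat_g
    )
  )
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' Read back a classified menu table
#'
#' Inverse of [write_classified_table()]: reconstructs the item tibble
#' and the classification tibble. Empty flag cells (excluded rows) are
#' restored as `FALSE` with `n_flags = 0`, matching the in-memory
#' convention that only assessed items can carry flags.
#'
#' @param path CSV written by [write_classified_table()].
#' @return list with elements `items` and `results`.
#' @export
read_classified_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    restaurant = readr::col_character(),
    item_name = readr::col_character(),
    major_category = readr::col_character(),
    sub_category = readr::col_character(),
    serving_unit = readr::col_character(),
    status = readr::col_character(),
    band = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  item_cols <- c("item_id", "restaurant", "item_name", "major_category",
                 "sub_category", "serving_size", "serving_unit",
                 "calories_kcal", "sodium_mg", "sugars_g", "satfat_g")
  items <- raw[intersect(item_cols, names(raw))]
  restore_flag <- function(f) {
    out <- !is.na(f) & f == 1
    out
  }
  results <- tibble::tibble(
    item_id = raw$item_id,
    status = raw$status,
    band = raw$band,
    flag_sodium = restore_flag(raw$flag_sodium),
    flag_sugars = restore_flag(raw$flag_sugars),
    flag_satfat = restore_flag(raw$flag_satfat),
    n_flags = as.integer(ifelse(is.na(raw$n_flags), 0L, raw$n_flags)),
    thr_sodium_mg = raw$thr_sodium_mg,
    thr_sugars_g = raw$thr_sugars_g,
    thr_satfat_g = raw$thr_satfat_g
  )
  list(items = items, results = results)
}
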