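#' Load a front-of-package regulatory configuration
#'
#' Reads the YAML rule file describing daily values, serving-size bands,
#' per-band absolute thresholds, age profiles and exempt subcategories.
#' The shipped default reproduces the Canadian regulation as promulgated
#' (sodium 230/345/690 mg, total sugars 10/15/20 g, saturated fat
#' 2/3/6 g across the small/standard/large bands; sodium DV 2300 mg).
#'
#' The sugars large-band threshold is stored literally (20 g); it is not
#' recomputed as 30 % of the 100 g sugars DV. Setting
#' `options$sugars_large_g: 30` in the YAML selects the %DV-derived
#' variant instead.
#'
#' @param path path to a YAML rule file; `NULL` (default) loads the
#'   shipped Canadian configuration.
#' @return an object of class `fop_config`: a named list with elements
#'   `daily_values`, `bands`, `profiles`, `thresholds`, `options`,
#'   `exempt_subcategories`, `version`.
#' @examples
#' cfg <- fop_config()
#' cfg$thresholds$sodium_mg
#' @export
fop_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fop_rules_canada2022.yaml",
                        package = "menufop", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("regulatory config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cfg <- structure(raw, class = "fop_config")
  if (!is.null(cfg$options$sugars_large_g)) {
    cfg$thresholds$sugars_g$large <- cfg$options$sugars_large_g
  }
  validate_fop_config(cfg)
  cfg
}

validate_fop_config <- function(cfg) {
  dv <- cfg$daily_values
  if (is.null(dv$sodium_mg) || is.null(dv$sugars_g) || is.null(dv$satfat_g) ||
      any(unlist(dv) <= 0)) {
    stop("daily values must be present and positive", call. = FALSE)
  }
  if (is.null(cfg$bands$small_max_g) || cfg$bands$small_max_g <= 0) {
    stop("bands$small_max_g must be positive", call. = FALSE)
  }
  dvp <- unlist(cfg$bands$dv_percent[.band_levels])
  if (length(dvp) != 3 || any(diff(dvp) <= 0)) {
    stop("dv_percent must be strictly increasing small -> standard -> large",
         call. = FALSE)
  }
  for (p in cfg$profiles) {
    if (is.null(p$main_dish_cutoff_g) ||
        p$main_dish_cutoff_g <= cfg$bands$small_max_g) {
      stop("each profile needs main_dish_cutoff_g above small_max_g",
           call. = FALSE)
    }
  }
  for (key in unname(.nutrient_cols)) {
    thr <- unlist(cfg$thresholds[[key]][.band_levels])
    if (length(thr) != 3 || any(is.na(thr)) || any(thr <= 0)) {
      stop("thresholds$", key, " must give positive small/standard/large values",
           call. = FALSE)
    }
    if (any(diff(thr) < 0)) {
      stop("thresholds$", key, " must be non-decreasing with band size",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.fop_config <- function(x, ...) {
  cat("<fop_config> ", x$version, "\n", sep = "")
  cat("  daily values: sodium ", x$daily_values$sodium_mg, " mg, sugars ",
      x$daily_values$sugars_g, " g, sat fat ", x$daily_values$satfat_g,
      " g\n", sep = "")
  cat("  bands: small (0, ", x$bands$small_max_g, "] g; large cutoff ",
      x$profiles$adults_children_over4$main_dish_cutoff_g, " g (adults), ",
      x$profiles$children_1to4$main_dish_cutoff_g, " g (children 1-4 y)\n",
      sep = "")
  thr <- x$thresholds
  cat("  thresholds (small/standard/large):\n")
  cat("    sodium  ", paste(unlist(thr$sodium_mg[.band_levels]), collapse = "/"),
      " mg\n", sep = "")
  cat("    sugars  ", paste(unlist(thr$sugars_g[.band_levels]), collapse = "/"),
      " g\n", sep = "")
  cat("    sat fat ", paste(unlist(thr$satfat_g[.band_levels]), collapse = "/"),
      " g\n", sep = "")
  cat("  exempt subcategories: ",
      paste(vapply(x$exempt_subcategories,
                   function(e) paste0(e$major, "/", e$sub), character(1)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
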