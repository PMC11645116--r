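#' Validate a synthetic-menu generator configuration
#'
#' A generator configuration describes, per major category, the
#' subcategory mix and zero-inflated lognormal distributions for serving
#' size and nutrient amounts. Nutrient distributions are parameterised
#' by their arithmetic `mean` (zeros included) and log-scale SD `sigma`;
#' the log-mean is derived internally so the generating-distribution
#' mean equals `mean` exactly, which makes calibration targets explicit.
#'
#' @param config a named list with elements `n_items`, `category_mix`
#'   (named probabilities over the five major categories, summing to 1),
#'   `missing_serving_rate` in \[0, 1\], and `categories`: per major
#'   category a list with `sub_mix` (named probabilities summing to 1),
#'   `serving` (`unit`, `mean`, `sigma`), optional `serving_correlation`
#'   (Gaussian-copula correlation between serving size and nutrient
#'   amounts, default 0), and `nutrients` with `calories_kcal`,
#'   `sodium_mg`, `sugars_g`, `satfat_g`, each `mean`/`sigma`/`zero_p`.
#' @return the config, validated, with class `menu_generator_config`.
#' @seealso [calibrated_generator_config()] for the shipped calibrated
#'   recipe, [generate_menu()] to sample from it.
#' @export
generator_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$n_items) || config$n_items < 0) {
    stop("n_items must be a non-negative count", call. = FALSE)
  }
  mix <- unlist(config$category_mix)
  if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop("category_mix must be non-negative and sum to 1", call. = FALSE)
  }
  r <- config$missing_serving_rate
  if (is.null(r) || r < 0 || r > 1) {
    stop("missing_serving_rate must lie in [0, 1]", call. = FALSE)
  }
  for (major in names(mix)) {
    cat_cfg <- config$categories[[major]]
    if (is.null(cat_cfg)) {
      stop("no category distribution for ", major, call. = FALSE)
    }
    sub <- unlist(cat_cfg$sub_mix)
    if (abs(sum(sub) - 1) > 1e-8 || any(sub < 0)) {
      stop(major, ": sub_mix must be non-negative and sum to 1",
           call. = FALSE)
    }
    if (is.null(cat_cfg$serving$mean) || cat_cfg$serving$mean <= 0 ||
        is.null(cat_cfg$serving$sigma) || cat_cfg$serving$sigma < 0) {
      stop(major, ": serving needs mean > 0 and sigma >= 0", call. = FALSE)
    }
    rho <- cat_cfg$serving_correlation %||% 0
    if (abs(rho) > 1) {
      stop(major, ": serving_correlation must lie in [-1, 1]", call. = FALSE)
    }
    for (col in unname(.gen_nutrients)) {
      nd <- cat_cfg$nutrients[[col]]
      if (is.null(nd$mean) || nd$mean < 0 || is.null(nd$sigma) ||
          nd$sigma < 0) {
        stop(major, "/", col, ": nutrient needs mean >= 0 and sigma >= 0",
             call. = FALSE)
      }
      zp <- nd$zero_p %||% 0
      if (zp < 0 || zp >= 1) {
        stop(major, "/", col, ": zero_p must lie in [0, 1)", call. = FALSE)
      }
    }
  }
  structure(config, class = "menu_generator_config")
}

.gen_nutrients <- c("calories_kcal", "sodium_mg", "sugars_g", "satfat_g")

# log-mean giving arithmetic mean `mean` for a zero-inflated lognormal
lnorm_meanlog <- function(mean, sigma, zero_p = 0) {
  log(mean / (1 - zero_p)) - sigma^2 / 2
}

#' The shipped calibrated generator configuration
#'
#' Loads the Menu-FLIP-like recipe: five major categories with
#' subcategory mixes, right-skewed (lognormal) serving sizes and
#' nutrient amounts with category-specific locations (sodium
#' concentrated in entrées and starters, sugars in beverages and
#' desserts), a 29.2 % missing-serving-size rate, and exempt beverage
#' subcategories (alcohol, plain milk, water) weighted to give about
#' 1.4 % exempt items overall. Category-mean calibration targets with a
#' published value (e.g. entrées sodium 1232 mg, beverages sugars
#' 38.9 g, starters calories 665 kcal) are matched exactly by the
#' generating distributions; spreads are plausible fill-ins.
#'
#' @param n_items number of items to generate (default 18 760, the full
#'   dataset size the recipe emulates).
#' @param path alternative YAML recipe; `NULL` loads the shipped one.
#' @return a `menu_generator_config`.
#' @export
calibrated_generator_config <- function(n_items = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "menuflip2020_like.yaml",
                        package = "menufop", mustWork = TRUE)
  }
  config <- yaml::read_yaml(path)
  if (!is.null(n_items)) config$n_items <- n_items
  generator_config(config)
}

#' Generate a synthetic menu dataset
#'
#' Samples `n_items` menu items from a generator configuration:
#' categories and subcategories from their mixes, serving sizes and
#' nutrient amounts from zero-inflated lognormals (optionally rank-
#' correlated with serving size through a Gaussian copula), and
#' missing serving sizes completely at random at the configured rate.
#' Identical seed and configuration give identical datasets.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param n_restaurants number of synthetic chain labels to spread items
#'   over (default 141).
#' @return a menu tibble with the canonical columns of
#'   [read_menu_table()].
#' @examples
#' items <- generate_menu(calibrated_generator_config(n_items = 100), seed = 7)
#' table(items$major_category)
#' @export
generate_menu <- function(config, seed = 1L, n_restaurants = 141L) {
  config <- generator_config(unclass(config))
  n <- config$n_items

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  mix <- unlist(config$category_mix)
  major <- sample(names(mix), n, replace = TRUE, prob = mix)

  sub <- character(n)
  serving <- numeric(n)
  unit <- character(n)
  nut <- matrix(NA_real_, n, length(.gen_nutrients),
                dimnames = list(NULL, .gen_nutrients))
  for (m in names(mix)) {
    idx <- which(major == m)
    if (length(idx) == 0) next
    cc <- config$categories[[m]]
    sm <- unlist(cc$sub_mix)
    sub[idx] <- sample(names(sm), length(idx), replace = TRUE, prob = sm)
    s_sigma <- cc$serving$sigma
    s_mu <- lnorm_meanlog(cc$serving$mean, s_sigma)
    z_serv <- stats::rnorm(length(idx))
    serving[idx] <- exp(s_mu + s_sigma * z_serv)
    unit[idx] <- tolower(cc$serving$unit %||% "g")
    rho <- cc$serving_correlation %||% 0
    for (col in .gen_nutrients) {
      nd <- cc$nutrients[[col]]
      zp <- nd$zero_p %||% 0
      z <- rho * z_serv + sqrt(1 - rho^2) * stats::rnorm(length(idx))
      val <- if (nd$mean == 0) {
        rep(0, length(idx))
      } else if (nd$sigma == 0) {
        rep(nd$mean / (1 - zp), length(idx))
      } else {
        exp(lnorm_meanlog(nd$mean, nd$sigma, zp) + nd$sigma * z)
      }
      if (zp > 0) val[stats::runif(length(idx)) < zp] <- 0
      nut[idx, col] <- val
    }
  }

  missing <- stats::runif(n) < config$missing_serving_rate
  serving[missing] <- NA_real_
  unit[missing] <- NA_character_

  tibble::tibble(
    item_id = sprintf("item_%06d", seq_len(n)),
    restaurant = sprintf("chain_%03d",
                         sample.int(n_restaurants, n, replace = TRUE)),
    item_name = paste0(sub, " ", seq_len(n)),
    major_category = major,
    sub_category = sub,
    serving_size = serving,
    serving_unit = unit,
    calories_kcal = nut[, "calories_kcal"],
    sodium_mg = nut[, "sodium_mg"],
    sugars_g = nut[, "sugars_g"],
    satfat_g = nut[, "satfat_g"]
  )
}

#' Closed-form expected "high-in" flag rates for one category
#'
#' Analytic ground truth for the independence case: with serving size S
#' and nutrient amount X independent, the flag probability is
#' `sum over bands b of P(S in b) * P(X >= threshold_b)`, each factor
#' from the (zero-inflated) lognormal distribution function. Used as the
#' oracle against which pipeline flag rates on generated data are
#' checked. Rates are conditional on assessment (exemption and
#' missingness do not enter: missingness is independent of the amounts,
#' and exemption is a property of subcategory labels, not amounts).
#'
#' @param dist one category's distribution list (element of
#'   `config$categories`), with `serving`, `nutrients`, and
#'   `serving_correlation` 0 or absent.
#' @param config an [fop_config()] object.
#' @param profile age profile (sets the large-band cutoff).
#' @return named numeric vector: flag probabilities for `sodium`,
#'   `sugars`, `satfat`.
#' @section Errors: a non-zero `serving_correlation` is an error — the
#'   factorisation no longer holds; use a Monte-Carlo estimate instead.
#' @export
expected_flag_rate <- function(dist, config = fop_config(),
                               profile = "adults_children_over4") {
  rho <- dist$serving_correlation %||% 0
  if (rho != 0) {
    stop("closed form requires independent serving and nutrients ",
         "(serving_correlation = 0); use a Monte-Carlo estimate",
         call. = FALSE)
  }
  cutoff <- config$profiles[[profile]]$main_dish_cutoff_g
  small_max <- config$bands$small_max_g

  s_sigma <- dist$serving$sigma
  if (s_sigma == 0) {
    s <- dist$serving$mean
    band <- select_band(s, profile, config)
    p_band <- stats::setNames(as.numeric(.band_levels == band), .band_levels)
  } else {
    s_mu <- lnorm_meanlog(dist$serving$mean, s_sigma)
    p_small <- stats::plnorm(small_max, s_mu, s_sigma)
    p_large <- 1 - stats::plnorm(cutoff, s_mu, s_sigma)
    p_band <- c(small = p_small, standard = 1 - p_small - p_large,
                large = p_large)
  }

  out <- stats::setNames(numeric(3), .nutrients)
  for (nutr in .nutrients) {
    nd <- dist$nutrients[[.nutrient_cols[[nutr]]]]
    zp <- nd$zero_p %||% 0
    thr <- threshold_for(nutr, .band_levels, config)
    p_exceed <- if (nd$mean == 0) {
      rep(0, 3)
    } else if (nd$sigma == 0) {
      (1 - zp) * as.numeric(nd$mean / (1 - zp) >= thr)
    } else {
      mu <- lnorm_meanlog(nd$mean, nd$sigma, zp)
      (1 - zp) * (1 - stats::plnorm(thr, mu, nd$sigma))
    }
    out[nutr] <- sum(p_band * p_exceed)
  }
  out
}
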