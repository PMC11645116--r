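# Shared fixtures: quick item builders, a random-item sampler that
# stresses band boundaries, and an independent brute-force classifier
# that inlines the regulatory flow chart literally (exemption first,
# then the missing-serving exclusion, then banded inclusive threshold
# comparisons). The oracle shares no code with classify_menu().

make_items <- function(n = 1, major = "entrees", sub = "burgers/sandwiches",
                       serving = 100, unit = "g", kcal = 500,
                       sodium = 100, sugars = 1, satfat = 1,
                       id = NULL) {
  tibble::tibble(
    item_id = id %||% sprintf("it_%03d", seq_len(n)),
    restaurant = "chain_001",
    item_name = paste("item", seq_len(n)),
    major_category = rep_len(major, n),
    sub_category = rep_len(sub, n),
    serving_size = rep_len(serving, n),
    serving_unit = rep_len(unit, n),
    calories_kcal = rep_len(kcal, n),
    sodium_mg = rep_len(sodium, n),
    sugars_g = rep_len(sugars, n),
    satfat_g = rep_len(satfat, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random items spanning all categories, exempt subcategories, missing
# servings/nutrients, and exact threshold boundary values.
random_items <- function(n, seed = 1) {
  set.seed(seed)
  majors <- c("beverages", "desserts", "entrees", "sides", "starters")
  subs <- list(
    beverages = c("water", "plain milk", "alcohol", "soft drinks",
                  "juices/smoothies"),
    desserts = c("frozen desserts", "baked goods"),
    entrees = c("poutine", "pizza", "burgers/sandwiches"),
    sides = c("fries and onion rings", "salads"),
    starters = c("dips", "wings")
  )
  major <- sample(majors, n, replace = TRUE)
  sub <- vapply(major, function(m) sample(subs[[m]], 1), character(1))
  boundaryish <- function(n, pool) {
    x <- stats::runif(n, 0, max(pool) * 1.5)
    swap <- stats::runif(n) < 0.2
    x[swap] <- sample(pool, sum(swap), replace = TRUE)
    x
  }
  serving <- boundaryish(n, c(30, 170, 200))
  serving[stats::runif(n) < 0.25] <- NA_real_
  sodium <- boundaryish(n, c(230, 345, 690))
  sugars <- boundaryish(n, c(10, 15, 20))
  satfat <- boundaryish(n, c(2, 3, 6))
  sodium[stats::runif(n) < 0.05] <- NA_real_
  tibble::tibble(
    item_id = sprintf("rnd_%05d", seq_len(n)),
    restaurant = "chain_001",
    item_name = paste("random", seq_len(n)),
    major_category = major,
    sub_category = unname(sub),
    serving_size = serving,
    serving_unit = ifelse(major == "beverages", "ml", "g"),
    calories_kcal = stats::runif(n, 0, 1500),
    sodium_mg = sodium,
    sugars_g = sugars,
    satfat_g = satfat
  )
}

# Literal flow-chart classifier for one item (independent oracle).
oracle_classify <- function(item, cfg, profile = "adults_children_over4") {
  no_flags <- c(sodium = FALSE, sugars = FALSE, satfat = FALSE)
  is_ex <- FALSE
  for (e in cfg$exempt_subcategories) {
    if (tolower(e$major) == tolower(item$major_category) &&
        tolower(e$sub) == tolower(item$sub_category)) {
      is_ex <- TRUE
    }
  }
  if (is_ex) {
    return(list(status = "exempt", band = NA_character_, flags = no_flags,
                n_flags = 0L))
  }
  s <- item$serving_size
  if (is.na(s) || s <= 0) {
    return(list(status = "excluded_missing_serving", band = NA_character_,
                flags = no_flags, n_flags = 0L))
  }
  cutoff <- cfg$profiles[[profile]]$main_dish_cutoff_g
  band <- if (s <= cfg$bands$small_max_g) {
    "small"
  } else if (s >= cutoff) {
    "large"
  } else {
    "standard"
  }
  f <- c(
    sodium = !is.na(item$sodium_mg) &&
      item$sodium_mg >= cfg$thresholds$sodium_mg[[band]],
    sugars = !is.na(item$sugars_g) &&
      item$sugars_g >= cfg$thresholds$sugars_g[[band]],
    satfat = !is.na(item$satfat_g) &&
      item$satfat_g >= cfg$thresholds$satfat_g[[band]]
  )
  list(status = "assessed", band = band, flags = f,
       n_flags = as.integer(sum(f)))
}

oracle_classify_all <- function(items, cfg,
                                profile = "adults_children_over4") {
  lapply(seq_len(nrow(items)), function(i) {
    oracle_classify(as.list(items[i, ]), cfg, profile)
  })
}

# One known-by-hand set: 3 zero-flag, 4 one-flag, 2 two-flag, 1 three-flag.
ten_item_fixture <- function() {
  dplyr::bind_rows(
    make_items(3, serving = 100, sodium = 10, sugars = 1, satfat = 1,
               id = sprintf("z%02d", 1:3)),
    make_items(4, serving = 100, sodium = 400, sugars = 1, satfat = 1,
               id = sprintf("a%02d", 1:4)),
    make_items(2, serving = 100, sodium = 400, sugars = 20, satfat = 1,
               id = sprintf("b%02d", 1:2)),
    make_items(1, serving = 100, sodium = 400, sugars = 20, satfat = 4,
               id = "c01")
  )
}
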