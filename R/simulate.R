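#' Simulation configuration for synthetic catalogs
#'
#' Fixes every knob of the synthetic generic/branded catalog generator. All
#' randomness flows from `seed`; the same config yields bit-identical
#' catalogs. The defaults describe a desk-scale study: 5 food groups of 30
#' reference foods, 500 branded items derived from them with 5%
#' multiplicative label noise on the four ranking macronutrients, and no
#' injected errors unless requested.
#'
#' @param seed Integer seed.
#' @param n_groups Number of food groups.
#' @param n_generics_per_group Reference foods per group.
#' @param n_branded Branded items.
#' @param noise_sd_pct Log-normal noise standard deviation on the four
#'   ranking macros, in percent of the value.
#' @param error_rates Named list of injection probabilities:
#'   `decimal_shift`, `salt_swap`, `missing_panel`, `multipack`,
#'   `diet_variant` (all default 0).
#' @param blend_fraction Share of branded items built as two-generic blends
#'   on the 10% grid (requires at least 2 groups when positive).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_groups = 5, n_generics_per_group = 30,
                       n_branded = 500, noise_sd_pct = 5,
                       error_rates = list(), blend_fraction = 0) {
  defaults <- list(decimal_shift = 0, salt_swap = 0, missing_panel = 0,
                   multipack = 0, diet_variant = 0)
  error_rates <- utils::modifyList(defaults, error_rates)
  stopifnot(all(unlist(error_rates) >= 0), all(unlist(error_rates) <= 1),
            blend_fraction >= 0, blend_fraction <= 1, noise_sd_pct >= 0)
  structure(list(seed = as.integer(seed), n_groups = n_groups,
                 n_generics_per_group = n_generics_per_group,
                 n_branded = n_branded, noise_sd_pct = noise_sd_pct,
                 error_rates = error_rates, blend_fraction = blend_fraction),
            class = "sim_config")
}

with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sim_group_labels <- function(n) {
  base <- c("bakery", "dairy", "soft drinks", "meat", "vegetables",
            "snacks", "fish", "breakfast cereals", "sauces", "frozen foods",
            "alcoholic drinks", "fruit")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf(
    "group %02d", seq_len(n - length(base))))
}

sim_nouns <- c("loaf", "yoghurt", "cola", "sausage", "peas", "crisps",
               "fillet", "flakes", "relish", "bake", "ale", "compote",
               "roll", "spread", "squash", "pie", "soup", "bar")

#' Generate a synthetic generic reference catalog
#'
#' Draws, per food group, a macronutrient archetype (total macro mass and
#' protein/fat/carbohydrate composition) and then per-food profiles around
#' it. Energy follows from the Atwater factors (4/9/4 kcal per g of
#' protein/fat/carbohydrate), so every profile respects the global
#' plausibility cut-offs by construction (energy can never exceed 900
#' kcal/100 g at 100 g of pure fat). Saturates and sugars are fractions of
#' fat and carbohydrate; sodium and ten micronutrients are drawn per group
#' on a log scale.
#'
#' @param config A [sim_config()].
#' @return Tibble of generic foods (columns as [read_generic_catalog()]),
#'   with attribute `truth`: the per-group min/max range table actually
#'   generated.
#' @export
generate_generics <- function(config = sim_config()) {
  with_seed_(config$seed, {
    groups <- sim_group_labels(config$n_groups)
    rows <- list()
    micros <- micronutrient_keys()
    for (gi in seq_along(groups)) {
      n <- config$n_generics_per_group
      total0 <- stats::runif(1, 25, 90)               # macro g per 100 g
      w0 <- stats::rexp(3) + 0.15
      w0 <- w0 / sum(w0)                              # P/F/C composition
      sat0 <- stats::runif(1, 0.15, 0.6)
      sug0 <- stats::runif(1, 0.1, 0.8)
      sodium0 <- exp(stats::runif(1, log(30), log(1200)))
      for (i in seq_len(n)) {
        total <- min(total0 * stats::runif(1, 0.7, 1.3), 100)
        w <- w0 * (stats::rexp(3) + 1)
        w <- w / sum(w)
        protein <- min(total * w[1], 89)
        fat <- min(total * w[2], 99.9)
        carb <- min(total * w[3], 99.9)
        panel <- c(
          protein_g = protein, fat_g = fat, carb_g = carb,
          energy_kcal = min(4 * protein + 9 * fat + 4 * carb, 900),
          satfat_g = fat * sat0 * stats::runif(1, 0.7, 1.3),
          sugars_g = carb * min(sug0 * stats::runif(1, 0.7, 1.3), 1),
          fibre_g = stats::runif(1, 0, 12),
          sodium_mg = min(sodium0 * exp(stats::rnorm(1, 0, 0.4)), 15600))
        mic <- exp(stats::rnorm(length(micros), log(gi + i %% 7 + 1), 0.3))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          code = sprintf("G%02d-%03d", gi, i),
          description = sprintf("%s, %s %d", groups[gi],
                                sim_nouns[(gi + i) %% length(sim_nouns) + 1],
                                i),
          food_group = groups[gi],
          !!!panel, !!!stats::setNames(mic, micros))
      }
    }
    cat <- dplyr::bind_rows(rows)
    attr(cat, "truth") <- build_group_ranges(cat)
    cat
  })
}

noisy <- function(x, sd_pct) {
  if (sd_pct == 0) return(x)
  x * exp(stats::rnorm(length(x), 0, sd_pct / 100))
}

#' Generate a synthetic branded catalog from a generic catalog
#'
#' Each branded item is derived from one parent generic (or, for a
#' configured fraction, a two-generic blend with a known split on the 10%
#' grid) with log-normal multiplicative noise on the four ranking
#' macronutrients — label values are positive and their errors scale with
#' magnitude. Data pathologies seen in commercial label extracts are then
#' injected at configured rates and recorded in a truth table: decimal
#' shifts (one macro multiplied or divided by 10), salt/sodium swaps (the
#' sodium figure, in grams, written into the salt field), missing label
#' panels, multi-packs, and diet variants (sugars zeroed, energy cut to a
#' few percent of the parent).
#'
#' @param config A [sim_config()].
#' @param generics Catalog from [generate_generics()].
#' @return Branded catalog tibble with attribute `truth`: one row per item
#'   (`item_id`, `parent_code`, `parent_code_2`, `split_pct`, `error_type`,
#'   `error_nutrient`, `original_value`).
#' @export
generate_branded <- function(config = sim_config(),
                             generics = generate_generics(config)) {
  stopifnot(nrow(generics) > 0)
  if (config$blend_fraction > 0 &&
      length(unique(generics$food_group)) < 2) {
    stop("blend_fraction > 0 requires at least 2 food groups", call. = FALSE)
  }
  with_seed_(config$seed + 1L, {
    n <- config$n_branded
    rates <- config$error_rates
    brands <- c("Aldmore", "Berrys", "Caldwell", "Dunmore", "Eastgate",
                "Fenwick")
    ranking <- c("energy_kcal", "fat_g", "protein_g", "carb_g")
    other <- setdiff(bop_nutrients(), ranking)
    n_blend <- round(config$blend_fraction * n)
    is_blend <- seq_len(n) <= n_blend
    rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("B%05d", i)
      brand <- sample(brands, 1)
      if (is_blend[i]) {
        p1 <- sample(nrow(generics), 1)
        pool <- which(generics$food_group != generics$food_group[p1])
        p2 <- pool[sample(length(pool), 1)]
        split <- sample(seq(10, 90, 10), 1)
        alloc <- tibble::tibble(
          generic_code = c(generics$code[p1], generics$code[p2]),
          percent = c(split, 100 - split))
        panel <- blend_panel(alloc, generics, keys = bop_nutrients())
        desc <- sprintf("%s %s with %s", brand, generics$description[p1],
                        generics$description[p2])
        tr <- tibble::tibble(item_id = id,
                             parent_code = generics$code[p1],
                             parent_code_2 = generics$code[p2],
                             split_pct = split, error_type = NA_character_,
                             error_nutrient = NA_character_,
                             original_value = NA_real_)
        group <- generics$food_group[p1]
      } else {
        p1 <- sample(nrow(generics), 1)
        panel <- unlist(generics[p1, bop_nutrients()])
        desc <- sprintf("%s %s", brand, generics$description[p1])
        tr <- tibble::tibble(item_id = id,
                             parent_code = generics$code[p1],
                             parent_code_2 = NA_character_,
                             split_pct = NA_real_,
                             error_type = NA_character_,
                             error_nutrient = NA_character_,
                             original_value = NA_real_)
        group <- generics$food_group[p1]
      }
      panel[ranking] <- noisy(panel[ranking], config$noise_sd_pct)
      pack_weight <- NA_real_
      multipack <- NA_real_

      if (!is_blend[i] && stats::runif(1) < rates$diet_variant) {
        tr$error_type <- "diet_variant"
        tr$error_nutrient <- "energy_kcal"
        tr$original_value <- panel[["energy_kcal"]]
        panel[["energy_kcal"]] <- panel[["energy_kcal"]] * 0.03
        panel[["sugars_g"]] <- 0
        panel[["carb_g"]] <- panel[["carb_g"]] * 0.05
        desc <- paste("diet", desc)
      }
      salt <- salt_from_sodium(panel[["sodium_mg"]])
      if (stats::runif(1) < rates$salt_swap && is.na(tr$error_type)) {
        tr$error_type <- "salt_swap"
        tr$error_nutrient <- "salt_g"
        tr$original_value <- salt
        salt <- panel[["sodium_mg"]] / 1000
      }
      if (stats::runif(1) < rates$decimal_shift && is.na(tr$error_type)) {
        key <- sample(bop_nutrients(), 1)
        tr$error_type <- "decimal_shift"
        tr$error_nutrient <- key
        tr$original_value <- panel[[key]]
        panel[[key]] <- panel[[key]] *
          (if (stats::runif(1) < 0.5) 10 else 0.1)
      }
      if (stats::runif(1) < rates$multipack) {
        multipack <- sample(2:6, 1)
        pack_weight <- multipack * stats::runif(1, 25, 150)
        desc <- sprintf("%s %d pack", desc, multipack)
      } else if (stats::runif(1) < 0.5) {
        pack_weight <- stats::runif(1, 100, 1000)
      }
      if (stats::runif(1) < rates$missing_panel && is.na(tr$error_type)) {
        drop <- sample(bop_nutrients(),
                       sample(length(bop_nutrients()), 1))
        tr$error_type <- "missing_panel"
        tr$error_nutrient <- paste(drop, collapse = ";")
        panel[drop] <- NA_real_
        if ("sodium_mg" %in% drop) salt <- NA_real_
      }
      rows[[i]] <- tibble::tibble(
        item_id = id, description = desc, brand = brand,
        barcode = sprintf("5%012d", i), food_group = group,
        !!!panel, salt_g = salt, pack_weight_g = pack_weight,
        multipack_count = multipack, is_food = TRUE, status = "active")
      truth[[i]] <- tr
    }
    cat <- dplyr::bind_rows(rows)
    attr(cat, "truth") <- dplyr::bind_rows(truth)
    cat
  })
}
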