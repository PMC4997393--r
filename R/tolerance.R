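#' EU food-labelling tolerance rules
#'
#' The EU Food Information to Consumers (FIC) guidance allows a declared
#' nutrition value to differ from the measured value within banded
#' tolerances that include measurement uncertainty. This table encodes the
#' bands used for back-of-pack auditing: carbohydrate, sugars, protein and
#' fibre (+/-2 g below 10 g/100 g, +/-20% from 10-40 g, +/-8 g above 40 g);
#' fat (+/-1.5 g below 10 g, then the same 20%/8 g bands); saturates
#' (+/-0.8 g below 4 g, +/-20% at or above); sodium on a gram basis
#' (+/-0.15 g below 0.5 g, +/-20% at or above); salt (+/-0.375 g below
#' 1.25 g, +/-20% at or above); vitamins (+50%/-35%) and minerals
#' (+45%/-35%) as asymmetric percentages.
#'
#' Band boundaries: "<10 g" means `[0, 10)`, "10-40 g" means `[10, 40]`,
#' ">40 g" means `(40, Inf)`; the "at least" thresholds (4 g saturates,
#' 0.5 g sodium, 1.25 g salt) are inclusive on the upper rule.
#'
#' @param vitamin_c_liquid_multiplier Optional multiplier (> 1) applied to
#'   the vitamin upper tolerance, for the allowance that liquids fortified
#'   with vitamin C may exceed the standard upper tolerance. Default 1 (off).
#' @return Named list of band tables used by [tolerance_bounds()].
#' @export
tolerance_rules <- function(vitamin_c_liquid_multiplier = 1) {
  stopifnot(vitamin_c_liquid_multiplier >= 1)
  gband <- function(lo, hi, type, amount) {
    tibble::tibble(lo = lo, hi = hi, type = type, amount = amount)
  }
  carb_like <- dplyr::bind_rows(
    gband(0, 10, "abs", 2), gband(10, 40, "pct", 20),
    gband(40, Inf, "abs", 8))
  fat <- dplyr::bind_rows(
    gband(0, 10, "abs", 1.5), gband(10, 40, "pct", 20),
    gband(40, Inf, "abs", 8))
  sat <- dplyr::bind_rows(gband(0, 4, "abs", 0.8), gband(4, Inf, "pct", 20))
  sodium <- dplyr::bind_rows(gband(0, 0.5, "abs", 0.15),
                             gband(0.5, Inf, "pct", 20))
  salt <- dplyr::bind_rows(gband(0, 1.25, "abs", 0.375),
                           gband(1.25, Inf, "pct", 20))
  list(
    carb_g = carb_like, sugars_g = carb_like, protein_g = carb_like,
    fibre_g = carb_like, fat_g = fat, satfat_g = sat,
    sodium_g = sodium, salt_g = salt,
    vitamin = list(up_pct = 50 * vitamin_c_liquid_multiplier, down_pct = 35),
    mineral = list(up_pct = 45, down_pct = 35)
  )
}

resolve_tolerance_key <- function(nutrient_key,
                                  registry = nutrient_registry()) {
  known <- c("carb_g", "sugars_g", "protein_g", "fibre_g", "fat_g",
             "satfat_g", "sodium_g", "salt_g", "vitamin", "mineral")
  if (nutrient_key %in% known) return(nutrient_key)
  cls <- registry$class[match(nutrient_key, registry$key)]
  if (!is.na(cls) && cls %in% c("vitamin", "mineral")) return(cls)
  stop("no tolerance rule for nutrient key: ", nutrient_key, call. = FALSE)
}

#' Tolerance interval around a declared value
#'
#' @param nutrient_key One of the banded macronutrient keys (`fat_g`,
#'   `satfat_g`, `carb_g`, `sugars_g`, `protein_g`, `fibre_g`, `sodium_g` —
#'   gram basis — or `salt_g`), the classes `"vitamin"` / `"mineral"`, or a
#'   registered micronutrient key, which resolves through its registry class.
#' @param declared Declared value per 100 g (gram basis for sodium).
#' @param rules A [tolerance_rules()] list.
#' @param registry A [nutrient_registry()] for micronutrient class lookup.
#' @return Named numeric `c(low, high)`; the declared value always lies
#'   inside.
#' @examples
#' tolerance_bounds("fat_g", 5)        # 5 +/- 1.5
#' tolerance_bounds("carb_g", 25)      # 25 +/- 20%
#' tolerance_bounds("vitamin", 100)    # +50% / -35%
#' @export
tolerance_bounds <- function(nutrient_key, declared,
                             rules = tolerance_rules(),
                             registry = nutrient_registry()) {
  stopifnot(declared >= 0)
  key <- resolve_tolerance_key(nutrient_key, registry)
  rule <- rules[[key]]
  if (key %in% c("vitamin", "mineral")) {
    return(c(low = declared * (1 - rule$down_pct / 100),
             high = declared * (1 + rule$up_pct / 100)))
  }
  # [lo, hi) bands, except the middle 20% band keeps its upper edge:
  # <10 g is [0,10), 10-40 g is [10,40], >40 g is (40, Inf)
  band <- which(declared >= rule$lo & declared < rule$hi)
  if (length(band) == 0) band <- nrow(rule)
  if (band == nrow(rule) && nrow(rule) == 3 && declared == rule$lo[3]) {
    band <- 2L
  }
  tol <- if (rule$type[band] == "abs") {
    rule$amount[band]
  } else {
    declared * rule$amount[band] / 100
  }
  c(low = max(declared - tol, 0), high = declared + tol)
}

#' Check a reference value against the declared value's tolerance interval
#'
#' @inheritParams tolerance_bounds
#' @param reference Independently measured / reference value per 100 g.
#' @return Tibble with `ok` (is `reference` within bounds), `margin` (signed
#'   distance past the violated bound; 0 when inside), `low`, `high`.
#' @export
within_tolerance <- function(nutrient_key, declared, reference,
                             rules = tolerance_rules(),
                             registry = nutrient_registry()) {
  b <- tolerance_bounds(nutrient_key, declared, rules, registry)
  margin <- if (reference > b[["high"]]) {
    reference - b[["high"]]
  } else if (reference < b[["low"]]) {
    reference - b[["low"]]
  } else 0
  tibble::tibble(ok = margin == 0, margin = margin,
                 low = b[["low"]], high = b[["high"]])
}

#' Negligible-amount label declaration
#'
#' Below fixed concentrations a nutrient need not be declared numerically:
#' sugars, fat, carbohydrate and protein at or below 0.5 g/100 g are
#' declared "<0.5 g"; saturates at or below 0.1 g/100 g "<0.1 g"; salt at or
#' below 0.0125 g/100 g "<0.01 g" (the regulation's threshold and label are
#' printed with different precision; both are kept as printed). An exact
#' zero is declared "0 g".
#'
#' @param nutrient_key Nutrient key.
#' @param value Value in g per 100 g.
#' @return The declaration label, or `NA_character_` when the value must be
#'   declared numerically.
#' @examples
#' negligible_declaration("sugars_g", 0.3)   # "<0.5 g"
#' negligible_declaration("fat_g", 0)        # "0 g"
#' @export
negligible_declaration <- function(nutrient_key, value) {
  stopifnot(value >= 0)
  threshold <- switch(nutrient_key,
    sugars_g = , fat_g = , carb_g = , protein_g = 0.5,
    satfat_g = 0.1,
    salt_g = 0.0125,
    return(NA_character_))
  if (value > threshold) return(NA_character_)
  if (value == 0) return("0 g")
  label <- switch(nutrient_key, satfat_g = "<0.1 g", salt_g = "<0.01 g",
                  "<0.5 g")
  label
}
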