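#' Back-of-pack nutrient keys
#'
#' The eight nutrients legally framed on UK "Back of Pack" (BOP) labels,
#' expressed per 100 g: energy (kcal), protein (g), fat (g), saturated fat
#' (g), carbohydrate (g), total sugars (g), AOAC fibre (g) and sodium (mg).
#'
#' @return Character vector of the eight BOP column names.
#' @export
bop_nutrients <- function() {
  c("energy_kcal", "protein_g", "fat_g", "satfat_g",
    "carb_g", "sugars_g", "fibre_g", "sodium_mg")
}

#' Nutrient registry
#'
#' Declares the unit and class of every nutrient column a catalog may carry.
#' Units are fixed per key: energy in kcal, sodium in mg, micronutrient keys
#' carry their unit as a suffix, everything else in g per 100 g. The
#' micronutrient panel is open-ended; the default registry ships a
#' representative set of ten vitamins and minerals in the style of the UK
#' reference food tables.
#'
#' @param micronutrients Optional tibble with columns `key`, `unit`, `class`
#'   (`"vitamin"` or `"mineral"`) replacing the default micronutrient set.
#' @return Tibble with columns `key`, `unit`, `class`.
#' @examples
#' nutrient_registry()
#' @export
nutrient_registry <- function(micronutrients = NULL) {
  macros <- tibble::tibble(
    key  = bop_nutrients(),
    unit = c("kcal", "g", "g", "g", "g", "g", "g", "mg"),
    class = "macro"
  )
  if (is.null(micronutrients)) {
    micronutrients <- tibble::tibble(
      key = c("iron_mg", "calcium_mg", "zinc_mg", "potassium_mg",
              "vitamin_c_mg", "thiamin_mg", "riboflavin_mg",
              "folate_ug", "vitamin_b12_ug", "vitamin_d_ug"),
      unit = c("mg", "mg", "mg", "mg", "mg", "mg", "mg", "ug", "ug", "ug"),
      class = c("mineral", "mineral", "mineral", "mineral",
                "vitamin", "vitamin", "vitamin", "vitamin", "vitamin",
                "vitamin")
    )
  } else {
    micronutrients <- tibble::as_tibble(micronutrients)
    stopifnot(all(c("key", "unit", "class") %in% names(micronutrients)))
  }
  dplyr::bind_rows(macros, micronutrients)
}

#' Micronutrient keys of a registry
#' @param registry A [nutrient_registry()] tibble.
#' @return Character vector of non-macro keys.
#' @export
micronutrient_keys <- function(registry = nutrient_registry()) {
  registry$key[registry$class != "macro"]
}

# salt (g/100 g) from sodium (mg/100 g); 2.5 is the EU labelling convention
salt_from_sodium <- function(sodium_mg) sodium_mg / 1000 * 2.5

#' Validate a catalog's nutrient panel invariants
#'
#' Checks that present values are non-negative, saturated fat does not exceed
#' total fat, sugars do not exceed carbohydrate (each within a 0.01 g slack
#' for label rounding), and any `salt_g` column agrees with `sodium_mg`
#' through the 2.5 conversion within `1e-6`.
#'
#' @param catalog Tibble with nutrient columns (missing values are `NA`).
#' @return Tibble of violations (`item`, `check`, `value`); zero rows when
#'   the catalog is consistent.
#' @export
validate_panels <- function(catalog) {
  id <- if ("item_id" %in% names(catalog)) catalog$item_id else catalog$code
  nut_cols <- intersect(
    c(bop_nutrients(), "salt_g", setdiff(names(catalog), character())),
    names(catalog)
  )
  nut_cols <- nut_cols[vapply(catalog[nut_cols], is.numeric, logical(1))]
  nut_cols <- setdiff(nut_cols, c("pack_weight_g", "multipack_count"))
  out <- list()
  for (col in nut_cols) {
    bad <- !is.na(catalog[[col]]) & catalog[[col]] < 0
    if (any(bad)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        item = id[bad], check = paste0("negative_", col),
        value = catalog[[col]][bad])
    }
  }
  pairwise <- function(small, big, check) {
    ok <- is.na(catalog[[small]]) | is.na(catalog[[big]]) |
      catalog[[small]] <= catalog[[big]] + 0.01
    if (any(!ok)) {
      tibble::tibble(item = id[!ok], check = check,
                     value = catalog[[small]][!ok])
    }
  }
  if (all(c("satfat_g", "fat_g") %in% names(catalog))) {
    out[[length(out) + 1L]] <- pairwise("satfat_g", "fat_g", "satfat_gt_fat")
  }
  if (all(c("sugars_g", "carb_g") %in% names(catalog))) {
    out[[length(out) + 1L]] <- pairwise("sugars_g", "carb_g", "sugars_gt_carb")
  }
  if (all(c("salt_g", "sodium_mg") %in% names(catalog))) {
    both <- !is.na(catalog$salt_g) & !is.na(catalog$sodium_mg)
    off <- both &
      abs(catalog$salt_g - salt_from_sodium(catalog$sodium_mg)) > 1e-6
    if (any(off)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        item = id[off], check = "salt_sodium_mismatch",
        value = catalog$salt_g[off])
    }
  }
  out <- purrr::compact(out)
  if (length(out) == 0) {
    tibble::tibble(item = character(), check = character(), value = double())
  } else {
    dplyr::bind_rows(out)
  }
}
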