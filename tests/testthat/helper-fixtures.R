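# Tiny hand-written catalogs used across test files.

tiny_generics <- function() {
  tibble::tibble(
    code = c("G001", "G002", "G003", "G004", "G005"),
    description = c("beer, lager", "cola, carbonated", "bread, white",
                    "cheese, cheddar", "spirits, vodka"),
    food_group = c("drinks", "drinks", "bakery", "dairy", "drinks"),
    energy_kcal = c(40, 42, 240, 410, 220),
    protein_g = c(0.3, 0, 8, 25, 0),
    fat_g = c(0, 0, 2, 34, 0),
    satfat_g = c(0, 0, 0.5, 21, 0),
    carb_g = c(3, 10.5, 46, 0.5, 0),
    sugars_g = c(2, 10.5, 3, 0.2, 0),
    fibre_g = c(0, 0, 2.5, 0, 0),
    sodium_mg = c(10, 20, 450, 700, 5),
    iron_mg = c(0.1, 0, 1.2, 0.4, 0),
    vitamin_c_mg = c(0, 0, 0, 0.5, 0))
}

tiny_branded <- function() {
  tibble::tibble(
    item_id = c("B1", "B2", "B3"),
    description = c("Brandy bread, white sliced", "Fizzo cola 330ml",
                    "Dale cheddar mature"),
    brand = c("Brandy", "Fizzo", "Dale"),
    barcode = NA_character_,
    food_group = c("bakery", "drinks", "dairy"),
    energy_kcal = c(245, 41, 405),
    protein_g = c(8.2, 0, 25.5),
    fat_g = c(2.1, 0, 33.5),
    satfat_g = c(0.5, 0, 21),
    carb_g = c(45, 10.2, 0.4),
    sugars_g = c(3.1, 10.2, 0.2),
    fibre_g = c(2.4, 0, 0),
    sodium_mg = c(430, 18, 690),
    pack_weight_g = c(800, 330, 350),
    multipack_count = NA_real_,
    is_food = TRUE,
    status = "active")
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

# independent naive scorer used as the ranking oracle: plain loops, no reuse
# of the package's vectorised path
naive_rank <- function(branded_row, generics, epsilon = 0.1, cap = 500) {
  keys <- c("energy_kcal", "fat_g", "protein_g", "carb_g")
  scores <- rep(NA_real_, nrow(generics))
  for (i in seq_len(nrow(generics))) {
    acc <- c()
    for (k in keys) {
      b <- branded_row[[k]]
      g <- generics[[k]][i]
      if (is.na(b) || is.na(g)) next
      pd <- 100 * (g - b) / max(b, epsilon)
      acc <- c(acc, min(abs(pd), cap))
    }
    if (length(acc) > 0) scores[i] <- mean(acc) * 4
  }
  ord <- order(scores, generics$code, na.last = NA)
  generics$code[ord]
}
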