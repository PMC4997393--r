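test_that("group ranges are per-group min/max with keyword resolution", {
  g <- tiny_generics()
  rt <- build_group_ranges(g)
  drinks_e <- rt[rt$group == "drinks" & rt$nutrient_key == "energy_kcal", ]
  expect_equal(drinks_e$min, 40)
  expect_equal(drinks_e$max, 220)
  expect_equal(drinks_e$n, 3)
  # keyword rule: only matching reference descriptions contribute
  rt2 <- build_group_ranges(
    g, group_mapping = list("fizzy" = list(keyword = "carbonated")))
  fe <- rt2[rt2$group == "fizzy" & rt2$nutrient_key == "energy_kcal", ]
  expect_equal(c(fe$min, fe$max, fe$n), c(42, 42, 1))
  # explicit reference-group list
  rt3 <- build_group_ranges(
    g, group_mapping = list("baked" = list(ref_groups = "bakery")))
  expect_equal(rt3$n[rt3$group == "baked" & rt3$nutrient_key == "fat_g"], 1)
  expect_error(
    build_group_ranges(g, list("ghost" = list(keyword = "zzzz"))),
    "ghost")
  # nutrient absent from all items of a group yields no row
  g2 <- g
  g2$fibre_g[g2$food_group == "dairy"] <- NA
  rt4 <- build_group_ranges(g2)
  expect_equal(nrow(rt4[rt4$group == "dairy" & rt4$nutrient_key == "fibre_g", ]),
               0)
})

test_that("energy agreement flags beyond the threshold, with magnitude kept", {
  g <- tiny_generics()
  b <- tiny_branded()
  b$energy_kcal <- c(240, 1, 410)    # B2: diet-drink pattern vs cola 42
  maps <- tibble::tibble(
    item_id = c("B1", "B2", "B3"), rank = 1L,
    generic_code = c("G003", "G002", "G004"), percent = 100,
    distance = 0, method = "auto_single")
  flags <- energy_agreement_check(b, maps, g)
  expect_equal(flags$item_id, "B2")
  expect_equal(flags$observed, 100 * (42 - 1) / 1)   # 4100%, kept unclamped
  # +50% not flagged at the default 100% threshold
  b2 <- b
  b2$energy_kcal <- c(240, 28, 410)  # cola 42 vs label 28: +50%
  expect_equal(nrow(energy_agreement_check(b2, maps, g)), 0)
  # equal energies never flag
  b3 <- b
  b3$energy_kcal <- c(240, 42, 410)
  expect_equal(nrow(energy_agreement_check(b3, maps, g)), 0)
})

test_that("range outliers flag strictly outside, report unchecked groups", {
  g <- tiny_generics()
  rt <- build_group_ranges(g)
  b <- tiny_branded()
  b$sugars_g[1] <- 120
  b$food_group[3] <- "exotic"
  res <- range_outlier_check(b, rt)
  expect_equal(res$unchecked, "B3")
  sflag <- res$flags[res$flags$nutrient_key == "sugars_g", ]
  expect_equal(sflag$item_id, "B1")
  expect_equal(sflag$rule_id, "group_range")
  # a value exactly at the group max is in range
  b2 <- tiny_branded()
  b2$energy_kcal[1] <- rt$max[rt$group == "bakery" &
                                rt$nutrient_key == "energy_kcal"]
  res2 <- range_outlier_check(b2[1, ], rt)
  expect_false("energy_kcal" %in% res2$flags$nutrient_key)
})

test_that("the reference catalog is self-consistent with its own ranges", {
  cfg <- sim_config(seed = 21, n_groups = 4, n_generics_per_group = 12)
  g <- generate_generics(cfg)
  rt <- build_group_ranges(g)
  gg <- dplyr::mutate(g, item_id = code)
  res <- range_outlier_check(gg, rt)
  expect_equal(nrow(res$flags), 0)
  expect_equal(length(res$unchecked), 0)
})

test_that("injected decimal shifts that exit their group range are all caught", {
  cfg <- sim_config(seed = 33, n_groups = 4, n_generics_per_group = 15,
                    n_branded = 300, noise_sd_pct = 0,
                    error_rates = list(decimal_shift = 0.15))
  g <- generate_generics(cfg)
  b <- generate_branded(cfg, g)
  truth <- attr(b, "truth")
  shifted <- truth[!is.na(truth$error_type) &
                     truth$error_type == "decimal_shift", ]
  expect_gt(nrow(shifted), 10)
  rt <- build_group_ranges(g)
  res <- range_outlier_check(b, rt)
  # sensitivity on shifts that exit the range: every one flagged
  for (i in seq_len(nrow(shifted))) {
    key <- shifted$error_nutrient[i]
    id <- shifted$item_id[i]
    grp <- b$food_group[b$item_id == id]
    r <- rt[rt$group == grp & rt$nutrient_key == key, ]
    val <- b[[key]][b$item_id == id]
    if (nrow(r) == 1 && !is.na(val) && (val < r$min || val > r$max)) {
      expect_true(any(res$flags$item_id == id &
                        res$flags$nutrient_key == key),
                  info = paste(id, key))
    }
  }
  # decimal-shift suggester proposes the inverse shift for those cases
  sug <- detect_decimal_shift(b, rt)
  hit <- sug[sug$item_id %in% shifted$item_id, ]
  expect_gt(nrow(hit), 0)
  orig <- shifted$original_value[match(hit$item_id, shifted$item_id)]
  expect_equal(hit$suggested, orig, tolerance = 1e-9)
})

test_that("resolutions conserve items and touch exactly the flagged values", {
  b <- tiny_branded()
  flags <- tibble::tibble(
    item_id = c("B1", "B1", "B2", "B3", "B3"),
    rule_id = "group_range",
    nutrient_key = c("sugars_g", "sodium_mg", "energy_kcal", "fat_g",
                     "carb_g"),
    observed = c(120, 9000, 950, 80, 50),
    bound_low = 0, bound_high = 1,
    resolution = "pending")
  res <- apply_resolutions(b, flags, tibble::tibble(
    flag_id = c(1L, 2L, 3L, 4L),
    outcome = c("keep", "update", "remove", "keep"),
    new_value = c(NA, 900, NA, NA)))
  expect_equal(res$catalog$sodium_mg[1], 900)
  expect_equal(res$catalog$sugars_g[1], b$sugars_g[1])  # kept untouched
  expect_equal(res$catalog$status, c("active", "hidden", "active"))
  # conservation: active + hidden = input
  expect_equal(sum(res$audit$items_active, res$audit$items_hidden), nrow(b))
  expect_equal(res$audit$values_changed, 1L)
  expect_equal(res$flags$resolution,
               c("kept", "updated", "removed", "kept", "pending"))
  # empty resolutions: untouched catalog, all pending
  res2 <- apply_resolutions(b, flags, tibble::tibble(
    flag_id = integer(), outcome = character(), new_value = double()))
  expect_equal(res2$catalog[, names(b)], b)
  expect_true(all(res2$flags$resolution == "pending"))
  expect_error(apply_resolutions(b, flags, tibble::tibble(
    flag_id = 99L, outcome = "keep", new_value = NA_real_)), "99")
  expect_error(apply_resolutions(b, flags, tibble::tibble(
    flag_id = 1L, outcome = "update", new_value = NA_real_)), "new_value")
})

test_that("removing an item closes all its open flags", {
  b <- tiny_branded()
  flags <- tibble::tibble(
    item_id = c("B1", "B1", "B1"), rule_id = "group_range",
    nutrient_key = c("sugars_g", "fat_g", "sodium_mg"),
    observed = 1, bound_low = 0, bound_high = 0.5, resolution = "pending")
  res <- apply_resolutions(b, flags, tibble::tibble(
    flag_id = 1L, outcome = "remove", new_value = NA_real_))
  expect_true(all(res$flags$resolution == "removed"))
  expect_equal(res$audit$items_hidden, 1L)
})

test_that("agreement report: hand-set differences average per group", {
  g <- tibble::tibble(
    code = c("R1", "R2", "R3", "R4"), description = "ref",
    food_group = "grp",
    energy_kcal = c(110, 90, 120, 100),
    protein_g = 1, fat_g = 1, carb_g = 1, satfat_g = 0.5, sugars_g = 0.5,
    fibre_g = 0, sodium_mg = 10)
  b <- tibble::tibble(
    item_id = c("I1", "I2", "I3", "I4"), description = "x", brand = "x",
    food_group = "grp", energy_kcal = c(100, 100, 100, 100),
    protein_g = 1, fat_g = 1, carb_g = 1)
  maps <- tibble::tibble(item_id = b$item_id, rank = 1L,
                         generic_code = g$code, percent = 100,
                         distance = 0, method = "auto_single")
  rep <- agreement_report(b, maps, g)
  # diffs are +10, -10, +20, 0 -> mean +5
  expect_equal(rep$groups$mean_pct_diff_energy, 5)
  expect_equal(rep$groups$count, 4)
  expect_equal(rep$groups$pct_of_total, 100)
  expect_equal(rep$pct_within_10, 75)   # the +20 item is outside
})

test_that("agreement report orders groups by descending count", {
  cfg <- sim_config(seed = 12, n_groups = 5, n_generics_per_group = 10,
                    n_branded = 120)
  g <- generate_generics(cfg)
  b <- generate_branded(cfg, g)
  maps <- rank_catalog(b, g, top_k = 1)
  rep <- agreement_report(b, maps, g)
  expect_true(all(diff(rep$groups$count) <= 0))
  expect_equal(sum(rep$groups$count), length(unique(maps$item_id)))
  expect_equal(sum(rep$groups$pct_of_total), 100)
})
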