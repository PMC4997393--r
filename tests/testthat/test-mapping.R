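test_that("pct_diff follows the label-denominator convention, clamps and floors", {
  expect_equal(pct_diff(100, 100), 0)
  expect_equal(pct_diff(100, 110), 10)
  expect_equal(pct_diff(100, 90), -10)
  # zero label value: floored denominator, clamped at the cap
  expect_equal(pct_diff(0, 42), 500)
  expect_equal(pct_diff(0, 42, cap = Inf), 42000)
  expect_true(is.na(pct_diff(NA, 10)))
})

test_that("panel distance is the rescaled mean of comparable differences", {
  b <- c(energy_kcal = 100, fat_g = 10, protein_g = 5, carb_g = 20)
  expect_equal(panel_distance(b, b), 0)
  g <- c(energy_kcal = 110, fat_g = 11, protein_g = 5, carb_g = 20)
  expect_equal(panel_distance(b, g), 20)   # |10| + |10| + 0 + 0
  # comparable on energy only: mean x 4 keeps the scale
  g2 <- c(energy_kcal = 105, fat_g = NA, protein_g = NA, carb_g = NA)
  expect_equal(panel_distance(b, g2), 20)  # 5 x 4
  g3 <- c(energy_kcal = NA, fat_g = NA, protein_g = NA, carb_g = NA)
  expect_true(is.na(panel_distance(b, g3)))
})

test_that("single ranking matches the naive oracle over random panels", {
  g <- tiny_generics()
  for (seed in 1:5) {
    set.seed(seed)
    b <- tibble::tibble(item_id = "X",
                        energy_kcal = runif(1, 0, 500),
                        fat_g = runif(1, 0, 40),
                        protein_g = runif(1, 0, 30),
                        carb_g = runif(1, 0, 60))
    got <- rank_single(b, g, top_k = 10)
    expect_equal(got$generic_code, naive_rank(b, g))
    expect_equal(got$rank, seq_len(nrow(got)))
    expect_equal(got$percent, rep(100, nrow(got)))
    expect_true(all(diff(got$distance) >= 0))
  }
})

test_that("oracle equivalence holds on a larger synthetic catalog", {
  cfg <- sim_config(seed = 3, n_groups = 4, n_generics_per_group = 5,
                    n_branded = 12)
  g <- generate_generics(cfg)
  b <- generate_branded(cfg, g)
  m <- rank_catalog(b, g, top_k = nrow(g))
  for (i in seq_len(nrow(b))) {
    expect_equal(m$generic_code[m$item_id == b$item_id[i]],
                 naive_rank(b[i, ], g))
  }
})

test_that("exact copies rank first and ties break lexicographically", {
  g <- tiny_generics()
  copy <- tibble::tibble(item_id = "C", energy_kcal = g$energy_kcal[4],
                         fat_g = g$fat_g[4], protein_g = g$protein_g[4],
                         carb_g = g$carb_g[4])
  top <- rank_single(copy, g, top_k = 1)
  expect_equal(top$generic_code, "G004")
  expect_equal(top$distance, 0)
  # duplicate panels tie; the smaller code wins
  gtie <- dplyr::bind_rows(g, dplyr::mutate(g[4, ], code = "G000"))
  expect_equal(rank_single(copy, gtie, top_k = 1)$generic_code, "G000")
  # top_k larger than the candidate list
  expect_equal(nrow(rank_single(copy, g[1:3, ], top_k = 5)), 3)
  # all candidates incomparable -> empty with warning
  nog <- dplyr::mutate(g, energy_kcal = NA_real_, fat_g = NA_real_,
                       protein_g = NA_real_, carb_g = NA_real_)
  expect_warning(out <- rank_single(copy, nog), "comparable")
  expect_equal(nrow(out), 0)
})

test_that("blend enumeration counts match the independent enumeration oracle", {
  g <- tiny_generics()
  b <- tiny_branded()[1, ]
  # oracle: count pair x split evaluations and distinct canonical keys
  oracle_counts <- function(codes_a, codes_b, step = 10) {
    keys <- character()
    n_eval <- 0
    for (a in codes_a) for (bb in codes_b) {
      for (p in seq(0, 100, step)) {
        n_eval <- n_eval + 1
        keys <- c(keys, if (p == 0) bb else if (p == 100) a else
          paste(a, p, bb))
      }
    }
    list(n_eval = n_eval, n_unique = length(unique(keys)))
  }
  r11 <- enumerate_blends(b, g[1, ], g[2, ], top_k = 100)
  o11 <- oracle_counts(g$code[1], g$code[2])
  expect_equal(attr(r11, "n_evaluations"), o11$n_eval)
  expect_equal(attr(r11, "n_candidates"), o11$n_unique)
  expect_equal(o11$n_unique, 11)      # 9 interior blends + 2 singles
  expect_equal(o11$n_eval, 11)

  r23 <- enumerate_blends(b, g[1:2, ], g[3:5, ], top_k = 5)
  o23 <- oracle_counts(g$code[1:2], g$code[3:5])
  expect_equal(attr(r23, "n_evaluations"), 66)   # 2 x 3 x 11
  expect_equal(attr(r23, "n_evaluations"), o23$n_eval)
  expect_equal(attr(r23, "n_candidates"), o23$n_unique)
})

test_that("a branded item built as an exact 40/60 blend is recovered", {
  g <- tiny_generics()
  keys <- c("energy_kcal", "fat_g", "protein_g", "carb_g")
  blend <- 0.4 * unlist(g[1, keys]) + 0.6 * unlist(g[3, keys])
  b <- tibble::tibble(item_id = "X", !!!blend)
  res <- enumerate_blends(b, g[1:2, ], g[3:4, ], top_k = 1)
  expect_equal(res$distance, rep(0, 2))
  expect_equal(res$generic_code, c("G001", "G003"))
  expect_equal(res$percent, c(40, 60))
})

test_that("blend_panel is the allocation-weighted panel with missing propagation", {
  g <- tiny_generics()
  single <- blend_panel(tibble::tibble(generic_code = "G004", percent = 100), g)
  expect_equal(single[["iron_mg"]], 0.4)
  two <- blend_panel(tibble::tibble(generic_code = c("G001", "G003"),
                                    percent = c(50, 50)), g)
  expect_equal(two[["iron_mg"]], (0.1 + 1.2) / 2)
  # linearity against hand arithmetic on every macro
  expect_equal(two[["energy_kcal"]], (40 + 240) / 2)
  # missing in a constituent -> missing in the blend
  g2 <- g
  g2$iron_mg[1] <- NA
  two2 <- blend_panel(tibble::tibble(generic_code = c("G001", "G003"),
                                     percent = c(50, 50)), g2)
  expect_true(is.na(two2[["iron_mg"]]))
  expect_error(blend_panel(tibble::tibble(generic_code = "nope",
                                          percent = 100), g), "nope")
  expect_error(blend_panel(tibble::tibble(generic_code = c("G001", "G003"),
                                          percent = c(50, 40)), g), "100")
})

test_that("blend linearity holds within 1e-9 over random allocations", {
  g <- tiny_generics()
  set.seed(99)
  for (i in 1:20) {
    p <- runif(1, 1, 99)
    codes <- sample(g$code, 2)
    got <- blend_panel(tibble::tibble(generic_code = codes,
                                      percent = c(p, 100 - p)), g)
    a <- unlist(g[match(codes[1], g$code), names(got)])
    b <- unlist(g[match(codes[2], g$code), names(got)])
    expect_equal(got, p / 100 * a + (1 - p / 100) * b, tolerance = 1e-9)
  }
})

test_that("apply_mappings fills micros, never touches label macros", {
  g <- tiny_generics()
  b <- tiny_branded()
  b$energy_kcal[2] <- 1   # diet-style label
  maps <- tibble::tibble(item_id = "B2", rank = 1L, generic_code = "G002",
                         percent = 100, distance = 0, method = "auto_single")
  res <- apply_mappings(b, maps, g)
  out <- res$catalog
  expect_equal(out$energy_kcal[out$item_id == "B2"], 1)     # label kept
  expect_equal(out$iron_mg[out$item_id == "B2"], 0)         # micro gained
  expect_setequal(res$unmapped, c("B1", "B3"))
  expect_equal(out$energy_kcal[out$item_id == "B1"], b$energy_kcal[1])
  # description_only fills macros too
  maps2 <- dplyr::mutate(maps, method = "description_only")
  out2 <- apply_mappings(b, maps2, g)$catalog
  expect_equal(out2$energy_kcal[out2$item_id == "B2"], 42)
  expect_error(apply_mappings(b, dplyr::mutate(maps, item_id = "ZZ"), g),
               "ZZ")
})

test_that("recipe mappings renormalise within the 0.5 point slack", {
  g <- tiny_generics()
  b <- tiny_branded()[1, ]
  alloc <- tibble::tibble(generic_code = c("G001", "G002", "G003"),
                          percent = c(30, 30, 40.4))
  res <- recipe_mapping(b, alloc, g)
  expect_equal(sum(res$percent), 100)
  expect_equal(res$method, rep("manual_recipe", 3))
  expect_true(res$distance[1] >= 0)
  expect_error(recipe_mapping(b, dplyr::mutate(alloc, percent = percent - 4), g),
               "99.5")
  # 23-ingredient recipe accepted
  set.seed(1)
  many <- tibble::tibble(
    generic_code = sprintf("G%03d", 1:5),
    percent = c(20, 20, 20, 20, 20))
  expect_equal(nrow(recipe_mapping(b, many, g)), 5)
})
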