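#' Distance configuration for candidate ranking
#'
#' Branded items are ranked against generic reference foods by the summed
#' absolute percentage difference on four label macronutrients: energy, fat,
#' protein and carbohydrate. This object fixes the numerical conventions the
#' label data forces us to choose: a floor on the denominator (diet drinks
#' declare 0–1 kcal), a cap on any single nutrient's contribution (so one
#' pathological nutrient cannot dominate the sum unboundedly), and the blend
#' grid step.
#'
#' @param ranking_nutrients Nutrient keys used for ranking, in order.
#' @param epsilon Denominator floor, in the nutrient's own unit. The
#'   percentage difference divides by the branded (label) value; `epsilon`
#'   keeps zero-labelled nutrients finite.
#' @param per_nutrient_cap Maximum absolute contribution of one nutrient, in
#'   percentage points.
#' @param step_percent Blend enumeration increment; must divide 100.
#' @return A list of class `distance_config`.
#' @export
distance_config <- function(ranking_nutrients = c("energy_kcal", "fat_g",
                                                  "protein_g", "carb_g"),
                            epsilon = 0.1, per_nutrient_cap = 500,
                            step_percent = 10) {
  stopifnot(epsilon > 0, per_nutrient_cap > 0,
            step_percent > 0, 100 %% step_percent == 0)
  structure(list(ranking_nutrients = ranking_nutrients, epsilon = epsilon,
                 per_nutrient_cap = per_nutrient_cap,
                 step_percent = step_percent),
            class = "distance_config")
}

#' Signed percentage difference between a label value and a reference value
#'
#' Computes `100 * (reference - branded) / max(branded, epsilon)`, clamped to
#' `[-cap, cap]`. The denominator is the branded (label) value, so the sign
#' reads as "how far the generic sits above the label": a diet drink labelled
#' 1 kcal mapped to a 42 kcal generic gives a large positive difference.
#' Missing values propagate as `NA` ("incomparable").
#'
#' @param branded,reference Non-negative values (vectorised).
#' @param epsilon Denominator floor.
#' @param cap Clamp magnitude in percentage points.
#' @return Signed percentage difference(s).
#' @examples
#' pct_diff(100, 110)   # +10
#' pct_diff(0, 42)      # clamps at +500
#' @export
pct_diff <- function(branded, reference, epsilon = 0.1, cap = 500) {
  out <- 100 * (reference - branded) / pmax(branded, epsilon)
  pmin(pmax(out, -cap), cap)
}

#' Ranking distance between a branded panel and a candidate panel
#'
#' The mean absolute percentage difference over the ranking nutrients present
#' in both panels, multiplied by the number of ranking nutrients — so a fully
#' populated panel yields the plain sum of the four percentage differences,
#' while a partially populated panel stays on a comparable scale.
#'
#' @param branded,candidate Named numeric vectors (or 1-row data frames)
#'   holding nutrient values per 100 g; `NA` means missing.
#' @param config A [distance_config()].
#' @return Non-negative score, or `NA` when no ranking nutrient is
#'   comparable.
#' @export
panel_distance <- function(branded, candidate, config = distance_config()) {
  b <- as_panel_vector(branded, config$ranking_nutrients)
  g <- as_panel_vector(candidate, config$ranking_nutrients)
  comparable <- !is.na(b) & !is.na(g)
  if (!any(comparable)) return(NA_real_)
  pd <- abs(pct_diff(b[comparable], g[comparable],
                     config$epsilon, config$per_nutrient_cap))
  mean(pd) * length(config$ranking_nutrients)
}

as_panel_vector <- function(x, keys) {
  if (is.data.frame(x)) x <- unlist(x[1, intersect(keys, names(x))])
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  found <- intersect(keys, names(x))
  out[found] <- as.numeric(x[found])
  out
}

# distances from one branded panel to every row of a generic macro matrix
score_against_matrix <- function(branded_vec, gmat, config) {
  keys <- config$ranking_nutrients
  acc <- matrix(NA_real_, nrow = nrow(gmat), ncol = length(keys))
  for (j in seq_along(keys)) {
    b <- branded_vec[[keys[j]]]
    if (is.na(b)) next
    acc[, j] <- abs(pct_diff(b, gmat[, keys[j]],
                             config$epsilon, config$per_nutrient_cap))
  }
  n_comp <- rowSums(!is.na(acc))
  score <- rowMeans(acc, na.rm = TRUE) * length(keys)
  score[n_comp == 0] <- NA_real_
  score
}

generic_macro_matrix <- function(generics, config) {
  keys <- config$ranking_nutrients
  m <- matrix(NA_real_, nrow = nrow(generics), ncol = length(keys),
              dimnames = list(generics$code, keys))
  for (k in intersect(keys, names(generics))) m[, k] <- generics[[k]]
  m
}

#' Rank single-generic mapping candidates for a branded item
#'
#' Scores every generic against the branded item's label macronutrients and
#' returns the `top_k` best matches in ascending distance order — the list a
#' nutritionist reviews to pick the mapping. Ties are broken by generic code
#' (lexicographic) so output is deterministic.
#'
#' @param branded A 1-row tibble (or named vector) with the BOP nutrients.
#' @param generics Generic catalog tibble.
#' @param config A [distance_config()].
#' @param top_k Number of candidates to return.
#' @return Mapping-result tibble (`item_id`, `rank`, `generic_code`,
#'   `percent`, `distance`, `method = "auto_single"`), zero rows (with a
#'   warning) when no generic is comparable.
#' @export
rank_single <- function(branded, generics, config = distance_config(),
                        top_k = 10) {
  stopifnot(nrow(generics) > 0)
  item_id <- branded_id(branded)
  b <- as_panel_vector(branded, config$ranking_nutrients)
  score <- score_against_matrix(b, generic_macro_matrix(generics, config),
                                config)
  ok <- !is.na(score)
  if (!any(ok)) {
    warning("no comparable generic candidates for item ", item_id,
            call. = FALSE)
    return(empty_mapping())
  }
  ord <- order(score[ok], generics$code[ok])
  keep <- utils::head(ord, top_k)
  tibble::tibble(
    item_id = item_id, rank = seq_along(keep),
    generic_code = generics$code[ok][keep], percent = 100,
    distance = score[ok][keep], method = "auto_single")
}

branded_id <- function(branded) {
  if (is.data.frame(branded) && "item_id" %in% names(branded)) {
    branded$item_id[1]
  } else if ("item_id" %in% names(branded)) {
    as.character(branded[["item_id"]])
  } else {
    NA_character_
  }
}

empty_mapping <- function() {
  tibble::tibble(item_id = character(), rank = integer(),
                 generic_code = character(), percent = double(),
                 distance = double(), method = character())
}

#' Enumerate two-group blend candidates for a branded item
#'
#' For composite products (e.g. breaded fish), compares the branded item
#' against every pairing of generics drawn from two food-group-limited lists,
#' sweeping the split from 0% through 100% in `step_percent` increments. The
#' degenerate 0%/100% splits collapse to single-generic candidates and are
#' de-duplicated by a canonical allocation key before ranking.
#'
#' @param branded 1-row tibble with BOP nutrients.
#' @param group_a,group_b Generic catalog tibbles (both non-empty).
#' @param config A [distance_config()].
#' @param top_k Candidates to return.
#' @return Mapping-result tibble (`method = "auto_blend"`), one row per
#'   allocation (blends contribute two rows sharing a rank), with attributes
#'   `n_evaluations` (pair x split scorings before de-duplication) and
#'   `n_candidates` (unique candidates scored).
#' @export
enumerate_blends <- function(branded, group_a, group_b,
                             config = distance_config(), top_k = 10) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  item_id <- branded_id(branded)
  keys <- config$ranking_nutrients
  b <- as_panel_vector(branded, keys)
  splits <- seq(0, 100, by = config$step_percent)
  amat <- generic_macro_matrix(group_a, config)
  bmat <- generic_macro_matrix(group_b, config)
  pairs <- expand.grid(ia = seq_len(nrow(group_a)), ib = seq_len(nrow(group_b)))
  grid <- tidyr::expand_grid(pairs, p = splits)
  n_evaluations <- nrow(grid)

  # canonical key: degenerate splits reduce to the single generic
  key <- ifelse(grid$p == 100, group_a$code[grid$ia],
         ifelse(grid$p == 0, group_b$code[grid$ib],
                paste0(group_a$code[grid$ia], ":", grid$p, "|",
                       group_b$code[grid$ib], ":", 100 - grid$p)))
  first <- !duplicated(key)
  grid <- grid[first, , drop = FALSE]
  key <- key[first]

  w <- grid$p / 100
  blend <- matrix(NA_real_, nrow = nrow(grid), ncol = length(keys),
                  dimnames = list(NULL, keys))
  for (k in keys) {
    va <- amat[grid$ia, k]
    vb <- bmat[grid$ib, k]
    blend[, k] <- ifelse(grid$p == 100, va,
                  ifelse(grid$p == 0, vb, w * va + (1 - w) * vb))
  }
  score <- score_against_matrix(b, blend, config)
  ok <- !is.na(score)
  if (!any(ok)) {
    warning("no comparable blend candidates for item ", item_id,
            call. = FALSE)
    out <- empty_mapping()
  } else {
    ord <- order(score[ok], key[ok])
    keep <- utils::head(ord, top_k)
    rows <- lapply(seq_along(keep), function(r) {
      i <- which(ok)[keep[r]]
      p <- grid$p[i]
      if (p == 100) {
        alloc <- tibble::tibble(generic_code = group_a$code[grid$ia[i]],
                                percent = 100)
      } else if (p == 0) {
        alloc <- tibble::tibble(generic_code = group_b$code[grid$ib[i]],
                                percent = 100)
      } else {
        alloc <- tibble::tibble(
          generic_code = c(group_a$code[grid$ia[i]],
                           group_b$code[grid$ib[i]]),
          percent = c(p, 100 - p))
      }
      tibble::tibble(item_id = item_id, rank = r,
                     generic_code = alloc$generic_code,
                     percent = alloc$percent,
                     distance = score[ok][keep[r]], method = "auto_blend")
    })
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "n_evaluations") <- n_evaluations
  attr(out, "n_candidates") <- length(key)
  out
}

#' Blend generic panels by percentage allocation
#'
#' Produces the allocation-weighted nutrient panel implied by a mapping:
#' every nutrient present in all constituent generics equals the weighted sum
#' `sum(percent/100 * value)`; a nutrient missing in any constituent is
#' missing in the blend (a partial sum would understate it).
#'
#' @param allocations Tibble with `generic_code` and `percent` columns;
#'   percents must sum to 100 within `1e-6`, codes must be distinct.
#' @param generics Generic catalog tibble.
#' @param keys Nutrient columns to blend; defaults to every registered
#'   nutrient column present in `generics`.
#' @return Named numeric vector of blended per-100 g values.
#' @export
blend_panel <- function(allocations, generics, keys = NULL) {
  stopifnot(nrow(allocations) > 0)
  if (anyDuplicated(allocations$generic_code) > 0) {
    stop("duplicate generic_code in allocation", call. = FALSE)
  }
  if (abs(sum(allocations$percent) - 100) > 1e-6) {
    stop("allocation percents must sum to 100", call. = FALSE)
  }
  unknown <- setdiff(allocations$generic_code, generics$code)
  if (length(unknown) > 0) {
    stop("allocation references unknown generic code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(keys)) {
    keys <- intersect(c(nutrient_registry()$key, "salt_g"), names(generics))
  }
  rows <- generics[match(allocations$generic_code, generics$code), keys,
                   drop = FALSE]
  w <- allocations$percent / 100
  out <- vapply(keys, function(k) {
    v <- rows[[k]]
    if (anyNA(v)) NA_real_ else sum(w * v)
  }, double(1))
  stats::setNames(out, keys)
}

#' Apply chosen mappings to a branded catalog
#'
#' Enriches each mapped branded item with the allocation-weighted
#' micronutrient panel of its generic constituents. The eight BOP
#' macronutrients are never overwritten — the label is the authority for
#' macros — with one exception: items mapped `description_only` had no label
#' panel, so both macros and micros are filled from the blend.
#'
#' @param branded Branded catalog tibble.
#' @param mappings Mapping table (`item_id`, `generic_code`, `percent`,
#'   `method`, optionally `rank` — only rank 1 / the best rank per item is
#'   applied).
#' @param generics Generic catalog tibble.
#' @param registry A [nutrient_registry()].
#' @return List: `catalog` (enriched tibble with micronutrient columns) and
#'   `unmapped` (item_ids that had no mapping and passed through unchanged).
#' @export
apply_mappings <- function(branded, mappings, generics,
                           registry = nutrient_registry()) {
  unknown <- setdiff(unique(mappings$item_id), branded$item_id)
  if (length(unknown) > 0) {
    stop("mapping references unknown item_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if ("rank" %in% names(mappings)) {
    mappings <- mappings |>
      dplyr::group_by(.data$item_id) |>
      dplyr::filter(.data$rank == min(.data$rank)) |>
      dplyr::ungroup()
  }
  micros <- intersect(micronutrient_keys(registry), names(generics))
  for (m in micros) if (!m %in% names(branded)) branded[[m]] <- NA_real_
  macros <- intersect(bop_nutrients(), names(branded))
  by_item <- split(mappings, mappings$item_id)
  for (id in names(by_item)) {
    alloc <- by_item[[id]]
    i <- match(id, branded$item_id)
    fill <- if (identical(alloc$method[1], "description_only")) {
      c(macros, micros)
    } else {
      micros
    }
    blended <- blend_panel(alloc[, c("generic_code", "percent")], generics,
                           keys = intersect(fill, names(generics)))
    for (k in names(blended)) branded[[k]][i] <- blended[[k]]
  }
  list(catalog = branded,
       unmapped = setdiff(branded$item_id, mappings$item_id))
}

#' Validate a hand-coded recipe mapping
#'
#' Ready meals and other composite products are often coded as a recipe of
#' many generic ingredients from the label's ingredient list. Percents are
#' accepted when they sum to 100 +/- 0.5 (nutritionists round), then
#' renormalised to exactly 100; the distance against the implied blend is
#' recorded for audit.
#'
#' @param branded 1-row tibble with BOP nutrients.
#' @param allocations Tibble (`generic_code`, `percent`), user supplied.
#' @param generics Generic catalog tibble.
#' @param config A [distance_config()].
#' @return Mapping-result tibble (`method = "manual_recipe"`, rank 1).
#' @export
recipe_mapping <- function(branded, allocations, generics,
                           config = distance_config()) {
  total <- sum(allocations$percent)
  if (total < 99.5 || total > 100.5) {
    stop("recipe allocation percents sum to ", format(total),
         "; must lie in [99.5, 100.5]", call. = FALSE)
  }
  allocations$percent <- allocations$percent / total * 100
  blended <- blend_panel(allocations[, c("generic_code", "percent")],
                         generics, keys = config$ranking_nutrients)
  d <- panel_distance(branded, blended, config)
  tibble::tibble(item_id = branded_id(branded), rank = 1L,
                 generic_code = allocations$generic_code,
                 percent = allocations$percent, distance = d,
                 method = "manual_recipe")
}

#' Rank the whole branded catalog against a generic catalog
#'
#' Convenience loop over [rank_single()] returning one combined mapping
#' table; the workhorse for batch mapping and for recovery experiments on
#' synthetic catalogs.
#'
#' @inheritParams rank_single
#' @param branded Branded catalog tibble.
#' @return Combined mapping-result tibble.
#' @export
rank_catalog <- function(branded, generics, config = distance_config(),
                         top_k = 10) {
  gmat <- generic_macro_matrix(generics, config)
  out <- vector("list", nrow(branded))
  for (i in seq_len(nrow(branded))) {
    b <- as_panel_vector(branded[i, ], config$ranking_nutrients)
    score <- score_against_matrix(b, gmat, config)
    ok <- !is.na(score)
    if (!any(ok)) next
    ord <- order(score[ok], generics$code[ok])
    keep <- utils::head(ord, top_k)
    out[[i]] <- tibble::tibble(
      item_id = branded$item_id[i], rank = seq_along(keep),
      generic_code = generics$code[ok][keep], percent = 100,
      distance = score[ok][keep], method = "auto_single")
  }
  dplyr::bind_rows(purrr::compact(out))
}
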