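#' Build per-group nutrient ranges from the reference catalog
#'
#' For each branded food group, resolves a set of reference foods (either an
#' explicit list of reference groups, a case-insensitive keyword matched
#' against reference descriptions — e.g. "frozen" for a frozen-foods group
#' with no reference equivalent — or, by default, the same group label) and
#' records the minimum and maximum of every nutrient over those foods.
#' These ranges are the outlier cut-offs for [range_outlier_check()].
#'
#' @param generics Generic (reference) catalog tibble.
#' @param group_mapping Named list: branded group -> list with optional
#'   elements `ref_groups` (character) and/or `keyword` (scalar). Groups not
#'   named fall back to an identical reference group label.
#' @param nutrients Nutrient columns to range over; default the eight BOP
#'   nutrients present in `generics`.
#' @return Tibble (`group`, `nutrient_key`, `min`, `max`, `n`); nutrients
#'   absent from every resolved item of a group produce no row.
#' @export
build_group_ranges <- function(generics, group_mapping = list(),
                               nutrients = NULL) {
  if (is.null(nutrients)) {
    nutrients <- intersect(bop_nutrients(), names(generics))
  }
  groups <- union(names(group_mapping), unique(generics$food_group))
  out <- list()
  for (g in groups) {
    rule <- group_mapping[[g]]
    sel <- rep(FALSE, nrow(generics))
    if (is.null(rule)) {
      sel <- generics$food_group == g
    } else {
      if (!is.null(rule$ref_groups)) {
        sel <- sel | generics$food_group %in% rule$ref_groups
      }
      if (!is.null(rule$keyword)) {
        sel <- sel | stringr::str_detect(tolower(generics$description),
                                         stringr::fixed(tolower(rule$keyword)))
      }
    }
    if (!any(sel)) {
      stop("group mapping resolves to zero reference items for group: ", g,
           call. = FALSE)
    }
    for (k in nutrients) {
      v <- generics[[k]][sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, nutrient_key = k, min = min(v), max = max(v),
        n = length(v))
    }
  }
  dplyr::bind_rows(out)
}

blended_energy <- function(mappings, generics) {
  if ("rank" %in% names(mappings)) {
    mappings <- mappings |>
      dplyr::group_by(.data$item_id) |>
      dplyr::filter(.data$rank == min(.data$rank)) |>
      dplyr::ungroup()
  }
  mappings |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(generic_energy = {
      v <- generics$energy_kcal[match(.data$generic_code, generics$code)]
      if (anyNA(v)) NA_real_ else sum(.data$percent / 100 * v)
    }, .groups = "drop")
}

#' Preliminary energy-agreement check after mapping
#'
#' Flags mapped items whose allocation-blended generic energy differs from
#' the label (BOP) energy by more than `threshold_pct` percent (of the label
#' value). Large differences are usually legitimate — diet products mapped
#' to non-diet generics — but each deserves a manual look; the observed
#' magnitude is kept on the flag so extreme (>1000%) cases stand out.
#'
#' @param catalog Branded catalog tibble (label energy in `energy_kcal`).
#' @param mappings Mapping table (`item_id`, `generic_code`, `percent`).
#' @param generics Generic catalog tibble.
#' @param threshold_pct Flag when `|pct_diff|` exceeds this, default 100.
#' @param config A [distance_config()] fixing epsilon and cap conventions;
#'   the cap is lifted to keep ">1000%" magnitudes distinguishable.
#' @return QC-flag tibble (`rule_id = "energy_agreement"`, `observed` = the
#'   signed percentage difference).
#' @export
energy_agreement_check <- function(catalog, mappings, generics,
                                   threshold_pct = 100,
                                   config = distance_config()) {
  be <- blended_energy(mappings, generics)
  bop <- catalog$energy_kcal[match(be$item_id, catalog$item_id)]
  pd <- pct_diff(bop, be$generic_energy, config$epsilon, cap = Inf)
  hit <- !is.na(pd) & abs(pd) > threshold_pct
  if (!any(hit)) return(empty_flags())
  tibble::tibble(item_id = be$item_id[hit], rule_id = "energy_agreement",
                 nutrient_key = "energy_kcal", observed = pd[hit],
                 bound_low = -threshold_pct, bound_high = threshold_pct,
                 resolution = "pending")
}

#' Flag nutrient values outside their food group's reference range
#'
#' One flag per (item, nutrient) strictly outside the `[min, max]` range the
#' reference catalog exhibits for that nutrient in the item's group; values
#' exactly on a bound are in range. A single item often flags on several of
#' the eight label nutrients. Items whose group has no range rows are
#' reported as unchecked rather than silently passed.
#'
#' @param catalog Branded catalog tibble.
#' @param range_table From [build_group_ranges()].
#' @return List: `flags` (QC-flag tibble, `rule_id = "group_range"`) and
#'   `unchecked` (item_ids in groups absent from the table).
#' @export
range_outlier_check <- function(catalog, range_table) {
  id_col <- if ("item_id" %in% names(catalog)) "item_id" else "code"
  unchecked <- catalog[[id_col]][
    !catalog$food_group %in% unique(range_table$group)]
  out <- list()
  for (i in seq_len(nrow(range_table))) {
    r <- range_table[i, ]
    if (!r$nutrient_key %in% names(catalog)) next
    idx <- which(catalog$food_group == r$group)
    vals <- catalog[[r$nutrient_key]][idx]
    hit <- !is.na(vals) & (vals < r$min | vals > r$max)
    if (!any(hit)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      item_id = catalog[[id_col]][idx][hit], rule_id = "group_range",
      nutrient_key = r$nutrient_key, observed = vals[hit],
      bound_low = r$min, bound_high = r$max, resolution = "pending")
  }
  flags <- if (length(out) == 0) empty_flags() else dplyr::bind_rows(out)
  list(flags = flags, unchecked = unchecked)
}

#' Apply manual resolutions to QC flags
#'
#' Each flagged value is checked against manufacturer information and
#' resolved one of three ways: `remove` — no data found, the product is
#' assumed discontinued and hidden; `update` — the product was reformulated
#' and the flagged nutrient is corrected to `new_value`; `keep` — the value
#' is corroborated and left untouched. Removing an item closes all of its
#' open flags. This is the only place in the toolkit where nutrient values
#' are mutated.
#'
#' @param catalog Branded catalog tibble (with a `status` column).
#' @param flags QC-flag tibble; rows are identified by position as
#'   `flag_id = seq_len(nrow(flags))` unless a `flag_id` column exists.
#' @param resolutions Tibble (`flag_id`, `outcome` in
#'   `c("keep", "update", "remove")`, `new_value` for updates).
#' @return List: `catalog` (updated), `flags` (with `resolution` filled),
#'   `audit` (one-row tibble of counts: kept, updated, removed flags, items
#'   hidden, values changed).
#' @export
apply_resolutions <- function(catalog, flags, resolutions) {
  if (!"flag_id" %in% names(flags)) {
    flags$flag_id <- seq_len(nrow(flags))
  }
  if (nrow(resolutions) > 0) {
    bad <- setdiff(resolutions$flag_id, flags$flag_id)
    if (length(bad) > 0) {
      stop("resolution references unknown flag id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stopifnot(all(resolutions$outcome %in% c("keep", "update", "remove")))
  }
  if (!"status" %in% names(catalog)) catalog$status <- "active"
  values_changed <- 0L
  for (i in seq_len(nrow(resolutions))) {
    res <- resolutions[i, ]
    fi <- match(res$flag_id, flags$flag_id)
    ci <- match(flags$item_id[fi], catalog$item_id)
    if (res$outcome == "keep") {
      flags$resolution[fi] <- "kept"
    } else if (res$outcome == "update") {
      if (!"new_value" %in% names(res) || is.na(res$new_value)) {
        stop("update resolution for flag ", res$flag_id,
             " lacks new_value", call. = FALSE)
      }
      catalog[[flags$nutrient_key[fi]]][ci] <- res$new_value
      flags$resolution[fi] <- "updated"
      values_changed <- values_changed + 1L
    } else {
      catalog$status[ci] <- "hidden"
      # hiding an item closes all of its open flags
      open <- flags$item_id == flags$item_id[fi] &
        flags$resolution == "pending"
      flags$resolution[open] <- "removed"
      flags$resolution[fi] <- "removed"
    }
  }
  audit <- tibble::tibble(
    flags_total = nrow(flags),
    flags_kept = sum(flags$resolution == "kept"),
    flags_updated = sum(flags$resolution == "updated"),
    flags_removed = sum(flags$resolution == "removed"),
    flags_pending = sum(flags$resolution == "pending"),
    items_hidden = sum(catalog$status == "hidden"),
    items_active = sum(catalog$status != "hidden"),
    values_changed = values_changed)
  list(catalog = catalog, flags = flags, audit = audit)
}

#' Per-group mapping agreement report
#'
#' Summarises, per food group, how closely the blended generic energy agrees
#' with the label energy across mapped items: item count, share of the
#' catalog, and the mean signed percentage difference (generic vs label).
#' Groups are ordered by descending count. The overall share of items within
#' 10% absolute agreement is attached, the headline statistic for a mapping
#' exercise of this kind.
#'
#' @inheritParams energy_agreement_check
#' @return List: `groups` (tibble `food_group`, `count`, `pct_of_total`,
#'   `mean_pct_diff_energy`) and `pct_within_10` (scalar, percent of mapped
#'   items with `|pct_diff| <= 10`).
#' @export
agreement_report <- function(catalog, mappings, generics,
                             config = distance_config()) {
  be <- blended_energy(mappings, generics)
  idx <- match(be$item_id, catalog$item_id)
  per_item <- tibble::tibble(
    item_id = be$item_id,
    food_group = catalog$food_group[idx],
    pd = pct_diff(catalog$energy_kcal[idx], be$generic_energy,
                  config$epsilon, config$per_nutrient_cap))
  per_item <- per_item[!is.na(per_item$pd), , drop = FALSE]
  groups <- per_item |>
    dplyr::group_by(.data$food_group) |>
    dplyr::summarise(count = dplyr::n(),
                     mean_pct_diff_energy = mean(.data$pd),
                     .groups = "drop") |>
    dplyr::mutate(pct_of_total = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count)) |>
    dplyr::select("food_group", "count", "pct_of_total",
                  "mean_pct_diff_energy")
  list(groups = groups,
       pct_within_10 = 100 * mean(abs(per_item$pd) <= 10))
}
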