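#' Default cleaning rule set
#'
#' Bundles the screens applied to a raw branded extract before mapping:
#' non-food keyword removal, seasonal-item removal, the multi-pack policy,
#' and the whole-database plausibility cut-offs (maximum credible value per
#' 100 g: energy 900 kcal — pure fats and oils; carbohydrate 99.9 g and
#' sugars 100 g — table sugar; protein 89 g — protein supplements; fat
#' 99.9 g; saturated fat 86 g — coconut oil and butter; fibre 54 g — dried
#' herbs; salt 39 g — seasoning mixes). Values above a cut-off are flagged
#' for manual inspection, never auto-corrected.
#'
#' @param nonfood_keywords,seasonal_keywords Character vectors matched
#'   case-insensitively as whole words against item descriptions.
#' @param multipack_policy `"remove_if_single_exists"` or `"keep"`.
#' @param global_cutoffs Named numeric maxima per 100 g; the defaults above.
#' @return A list of class `cleaning_rules`.
#' @export
cleaning_rules <- function(
    nonfood_keywords = c("cigarette", "cigarettes", "tobacco", "medicine",
                         "paracetamol", "vitamins supplement", "shampoo",
                         "nappies", "baby wipes", "pet food", "dog food",
                         "cat food"),
    seasonal_keywords = c("easter", "christmas", "advent", "halloween"),
    multipack_policy = c("remove_if_single_exists", "keep"),
    global_cutoffs = c(energy_kcal = 900, carb_g = 99.9, protein_g = 89,
                       sugars_g = 100, fat_g = 99.9, satfat_g = 86,
                       fibre_g = 54, salt_g = 39)) {
  multipack_policy <- match.arg(multipack_policy)
  structure(list(nonfood_keywords = nonfood_keywords,
                 seasonal_keywords = seasonal_keywords,
                 multipack_policy = multipack_policy,
                 global_cutoffs = global_cutoffs),
            class = "cleaning_rules")
}

matches_keyword <- function(descriptions, keywords) {
  if (length(keywords) == 0) return(rep(FALSE, length(descriptions)))
  pattern <- paste0("\\b(", paste(keywords, collapse = "|"), ")\\b")
  stringr::str_detect(tolower(descriptions), pattern)
}

#' Remove non-food items from a branded catalog
#'
#' An item is non-food when its `is_food` flag is `FALSE` or its description
#' matches a non-food keyword (case-insensitive, whole word). Cigarettes,
#' medicines and pet products routinely arrive in commercial label extracts.
#'
#' @param catalog Branded catalog tibble.
#' @param rules A [cleaning_rules()].
#' @return List of disjoint tibbles `kept` and `removed` partitioning the
#'   input.
#' @export
remove_nonfood <- function(catalog, rules = cleaning_rules()) {
  is_nonfood <- !catalog$is_food |
    matches_keyword(catalog$description, rules$nonfood_keywords)
  list(kept = catalog[!is_nonfood, , drop = FALSE],
       removed = catalog[is_nonfood, , drop = FALSE])
}

#' Remove seasonal-celebration items
#'
#' Seasonal products have limited shelf life and are unlikely to be on sale
#' in later years; a keyword screen on descriptions removes them.
#'
#' @inheritParams remove_nonfood
#' @return List of disjoint tibbles `kept` and `removed`.
#' @export
remove_seasonal <- function(catalog, rules = cleaning_rules()) {
  seasonal <- matches_keyword(catalog$description, rules$seasonal_keywords)
  list(kept = catalog[!seasonal, , drop = FALSE],
       removed = catalog[seasonal, , drop = FALSE])
}

#' Flag values above the global plausibility cut-offs
#'
#' One flag per (item, nutrient) pair strictly above its cut-off; a value
#' exactly at the cut-off is acceptable (the cut-offs are stated as maximum
#' plausible values). Salt is screened from `salt_g` when present, otherwise
#' computed from sodium via the 2.5 labelling convention.
#'
#' @inheritParams remove_nonfood
#' @return QC-flag tibble (`item_id`, `rule_id = "global_max"`,
#'   `nutrient_key`, `observed`, `bound_low`, `bound_high`, `resolution =
#'   "pending"`).
#' @export
flag_global_outliers <- function(catalog, rules = cleaning_rules()) {
  cutoffs <- rules$global_cutoffs
  salt <- if ("salt_g" %in% names(catalog)) catalog$salt_g else NA_real_
  if (all(is.na(salt)) && "sodium_mg" %in% names(catalog)) {
    salt <- salt_from_sodium(catalog$sodium_mg)
  }
  flags <- lapply(names(cutoffs), function(key) {
    vals <- if (key == "salt_g") salt else catalog[[key]]
    if (is.null(vals)) return(NULL)
    hit <- !is.na(vals) & vals > cutoffs[[key]]
    if (!any(hit)) return(NULL)
    tibble::tibble(item_id = catalog$item_id[hit], rule_id = "global_max",
                   nutrient_key = key, observed = vals[hit],
                   bound_low = 0, bound_high = cutoffs[[key]],
                   resolution = "pending")
  })
  flags <- purrr::compact(flags)
  if (length(flags) == 0) empty_flags() else dplyr::bind_rows(flags)
}

empty_flags <- function() {
  tibble::tibble(item_id = character(), rule_id = character(),
                 nutrient_key = character(), observed = double(),
                 bound_low = double(), bound_high = double(),
                 resolution = character())
}

#' Suggest decimal-shift corrections
#'
#' The most common data-entry error in label extracts is a decimal point
#' placed one position off. For every nutrient value outside its food
#' group's reference range, if dividing or multiplying by 10 brings it back
#' inside, a correction is suggested — never applied; corrections go through
#' the resolution workflow.
#'
#' @param catalog Branded catalog tibble.
#' @param range_table Group range table from [build_group_ranges()].
#' @return Suggestion tibble (`item_id`, `rule_id = "decimal_shift"`,
#'   `nutrient_key`, `observed`, `suggested`, `factor`).
#' @export
detect_decimal_shift <- function(catalog, range_table) {
  out <- list()
  for (i in seq_len(nrow(range_table))) {
    r <- range_table[i, ]
    idx <- which(catalog$food_group == r$group)
    if (length(idx) == 0 || !r$nutrient_key %in% names(catalog)) next
    vals <- catalog[[r$nutrient_key]][idx]
    oob <- !is.na(vals) & (vals < r$min | vals > r$max)
    if (!any(oob)) next
    v <- vals[oob]
    down_ok <- v / 10 >= r$min & v / 10 <= r$max
    up_ok <- v * 10 >= r$min & v * 10 <= r$max
    fixable <- down_ok | up_ok
    if (!any(fixable)) next
    factor <- ifelse(down_ok[fixable], 0.1, 10)
    out[[length(out) + 1L]] <- tibble::tibble(
      item_id = catalog$item_id[idx][oob][fixable],
      rule_id = "decimal_shift", nutrient_key = r$nutrient_key,
      observed = v[fixable], suggested = v[fixable] * factor,
      factor = factor)
  }
  if (length(out) == 0) {
    tibble::tibble(item_id = character(), rule_id = character(),
                   nutrient_key = character(), observed = double(),
                   suggested = double(), factor = double())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Suggest salt/sodium swap corrections
#'
#' A swapped entry puts the sodium figure (in g) in the salt field. The
#' pattern: salt equals sodium/1000 within 0.001 g while the expected salt
#' (sodium x 2.5 / 1000) differs from the declared salt by more than 20%.
#' Suggestions are never auto-applied.
#'
#' @param catalog Branded catalog tibble with `salt_g` and `sodium_mg`.
#' @return Suggestion tibble (`rule_id = "salt_sodium_swap"`) with the
#'   corrected pair (`suggested_salt_g`, `suggested_sodium_mg`).
#' @export
detect_salt_sodium_swap <- function(catalog) {
  empty <- tibble::tibble(item_id = character(), rule_id = character(),
                          salt_g = double(), sodium_mg = double(),
                          suggested_salt_g = double(),
                          suggested_sodium_mg = double())
  if (!all(c("salt_g", "sodium_mg") %in% names(catalog))) return(empty)
  both <- !is.na(catalog$salt_g) & !is.na(catalog$sodium_mg)
  expected <- salt_from_sodium(catalog$sodium_mg)
  swapped <- both &
    abs(catalog$salt_g - catalog$sodium_mg / 1000) < 1e-3 &
    abs(catalog$salt_g - expected) > 0.2 * pmax(expected, 1e-9)
  if (!any(swapped)) return(empty)
  tibble::tibble(
    item_id = catalog$item_id[swapped], rule_id = "salt_sodium_swap",
    salt_g = catalog$salt_g[swapped],
    sodium_mg = catalog$sodium_mg[swapped],
    suggested_salt_g = salt_from_sodium(catalog$sodium_mg[swapped]),
    suggested_sodium_mg = catalog$salt_g[swapped] * 1000)
}

normalize_description <- function(x) {
  x <- tolower(x)
  x <- stringr::str_replace_all(x, "\\d+\\s*(pack|x|multipack)", " ")
  x <- stringr::str_replace_all(x, "[[:punct:]]", " ")
  stringr::str_squish(x)
}

#' Collapse multi-pack items
#'
#' A multi-pack duplicates the nutrition of its single item. Where a
#' single-item twin exists (same brand, same description once pack-size
#' tokens are stripped), the multi-pack is removed; otherwise it is kept and
#' gains a "per item" portion of pack weight divided by item count.
#'
#' @inheritParams remove_nonfood
#' @return List: `kept`, `removed` (disjoint partition) and `portions`
#'   (tibble `item_id`, `label = "per item"`, `grams`, `source =
#'   "per_item"`).
#' @export
collapse_multipacks <- function(catalog, rules = cleaning_rules()) {
  count <- if ("multipack_count" %in% names(catalog)) {
    catalog$multipack_count
  } else {
    rep(NA_real_, nrow(catalog))
  }
  looks_multi <- stringr::str_detect(tolower(catalog$description),
                                     "\\d+\\s*(pack|x\\b|multipack)")
  is_multi <- (!is.na(count) & count >= 2) | looks_multi
  norm <- normalize_description(catalog$description)
  singles_key <- paste(catalog$brand, norm)[!is_multi]
  has_twin <- is_multi &
    paste(catalog$brand, norm) %in% singles_key &
    rules$multipack_policy == "remove_if_single_exists"
  keep_multi <- is_multi & !has_twin
  portions <- tibble::tibble(item_id = character(), label = character(),
                             grams = double(), source = character())
  idx <- which(keep_multi & !is.na(count) & count >= 2)
  has_weight <- idx[!is.na(catalog$pack_weight_g[idx])]
  no_weight <- setdiff(idx, has_weight)
  if (length(no_weight) > 0) {
    warning("multi-pack item(s) without pack weight kept without a per-item ",
            "portion: ", paste(catalog$item_id[no_weight], collapse = ", "),
            call. = FALSE)
  }
  if (length(has_weight) > 0) {
    portions <- tibble::tibble(
      item_id = catalog$item_id[has_weight], label = "per item",
      grams = catalog$pack_weight_g[has_weight] /
        catalog$multipack_count[has_weight],
      source = "per_item")
  }
  list(kept = catalog[!has_twin, , drop = FALSE],
       removed = catalog[has_twin, , drop = FALSE],
       portions = portions)
}

tokenize_description <- function(x) {
  toks <- stringr::str_split(stringr::str_squish(
    stringr::str_replace_all(tolower(x), "[^a-z0-9]+", " ")), " ")[[1]]
  sort(unique(toks[toks != ""]))
}

indel_similarity <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(1)
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
  1 - d / (nchar(a) + nchar(b))
}

#' Token-set similarity between two descriptions
#'
#' Order-insensitive fuzzy similarity on `[0, 1]`: both descriptions are
#' tokenised, and the maximum normalised indel similarity is taken over the
#' token intersection paired against each full sorted token string (so a
#' shared distinctive token scores highly even when one description carries
#' extra qualifiers).
#'
#' @param a,b Description strings.
#' @return Similarity in `[0, 1]`.
#' @examples
#' token_set_similarity("lager, 4% abv", "beer, lager")
#' @export
token_set_similarity <- function(a, b) {
  ta <- tokenize_description(a)
  tb <- tokenize_description(b)
  common <- intersect(ta, tb)
  s0 <- paste(common, collapse = " ")
  s1 <- paste(c(common, setdiff(ta, tb)), collapse = " ")
  s2 <- paste(c(common, setdiff(tb, ta)), collapse = " ")
  if (length(common) == 0) return(indel_similarity(s1, s2))
  max(indel_similarity(s0, s1), indel_similarity(s0, s2),
      indel_similarity(s1, s2))
}

#' Propose description-only mappings for items lacking label nutrients
#'
#' Items without a full label panel (alcoholic drinks are the classic case —
#' not legally required to carry one) cannot be mapped on nutrients, so the
#' best description match in the reference catalog is proposed instead; both
#' macronutrients and micronutrients would then be filled from the generic.
#' Items whose best similarity falls below the threshold are queued for
#' manual review.
#'
#' @param branded Branded catalog tibble.
#' @param generics Generic catalog tibble (non-empty).
#' @param threshold Minimum [token_set_similarity()] to propose, default
#'   0.6.
#' @return List: `proposals` (mapping tibble, `method = "description_only"`,
#'   with a `similarity` column) and `queued` (item_ids needing manual
#'   review). Items with a complete label panel are skipped.
#' @export
populate_missing_panels <- function(branded, generics, threshold = 0.6) {
  if (nrow(generics) == 0) stop("generic catalog is empty", call. = FALSE)
  bop <- intersect(bop_nutrients(), names(branded))
  incomplete <- rowSums(is.na(branded[bop])) > 0 | length(bop) < 8
  proposals <- list()
  queued <- character()
  for (i in which(incomplete)) {
    sims <- vapply(generics$description, token_set_similarity,
                   double(1), a = branded$description[i], USE.NAMES = FALSE)
    best <- which.max(sims)
    if (sims[best] >= threshold) {
      proposals[[length(proposals) + 1L]] <- tibble::tibble(
        item_id = branded$item_id[i], rank = 1L,
        generic_code = generics$code[best], percent = 100,
        distance = NA_real_, method = "description_only",
        similarity = sims[best])
    } else {
      queued <- c(queued, branded$item_id[i])
    }
  }
  proposals <- if (length(proposals) == 0) {
    dplyr::mutate(empty_mapping(), similarity = double())
  } else {
    dplyr::bind_rows(proposals)
  }
  list(proposals = proposals, queued = queued)
}

#' Run the full cleaning pass
#'
#' Applies non-food removal, seasonal removal and multi-pack collapsing in
#' order, and collects global-cut-off flags and salt/sodium swap suggestions
#' on the kept items. Values are never mutated: the pass only partitions,
#' flags and suggests, so running it twice equals running it once.
#'
#' @inheritParams remove_nonfood
#' @return List: `kept`, `removed` (with a `removal_reason` column),
#'   `flags`, `suggestions`, `portions`.
#' @export
clean_catalog <- function(catalog, rules = cleaning_rules()) {
  nf <- remove_nonfood(catalog, rules)
  se <- remove_seasonal(nf$kept, rules)
  mp <- collapse_multipacks(se$kept, rules)
  removed <- dplyr::bind_rows(
    dplyr::mutate(nf$removed, removal_reason = "nonfood"),
    dplyr::mutate(se$removed, removal_reason = "seasonal"),
    dplyr::mutate(mp$removed, removal_reason = "multipack_twin"))
  list(kept = mp$kept, removed = removed,
       flags = flag_global_outliers(mp$kept, rules),
       suggestions = detect_salt_sodium_swap(mp$kept),
       portions = mp$portions)
}
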