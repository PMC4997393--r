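#' Merge portion-size sources by priority
#'
#' Portion options come from several sources with a fixed priority: a
#' primary published table of standard serving weights wins; an averaged
#' fallback table (e.g. servings averaged from previously coded dietary
#' surveys) fills food types the primary table lacks; a plausible pack
#' weight is appended as a "whole pack" option; and per-item portions
#' derived from multi-pack collapsing are carried through. Merging never
#' drops an option an item already had.
#'
#' @param catalog Branded catalog tibble; the food type is taken from a
#'   `food_type` column when present, else `food_group`.
#' @param primary_table,fallback_table Tibbles (`food_type`, `label`,
#'   `grams`); `fallback_table` may be `NULL`.
#' @param per_item_portions Optional tibble from [collapse_multipacks()].
#' @param existing Optional tibble of options already attached
#'   (`item_id`, `label`, `grams`, `source`).
#' @param max_pack_g Pack weights above this are treated as catering sizes
#'   and not offered as a portion; default 5000 g.
#' @return Portion-option tibble (`item_id`, `label`, `grams`, `source`);
#'   labels are unique per item, `grams > 0`.
#' @export
merge_portion_sources <- function(catalog, primary_table,
                                  fallback_table = NULL,
                                  per_item_portions = NULL,
                                  existing = NULL, max_pack_g = 5000) {
  ft <- if ("food_type" %in% names(catalog)) {
    catalog$food_type
  } else {
    catalog$food_group
  }
  pick <- function(tab, type, source) {
    rows <- tab[tab$food_type == type, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    tibble::tibble(label = rows$label, grams = rows$grams, source = source)
  }
  out <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    opts <- pick(primary_table, ft[i], "fsa")
    if (is.null(opts) && !is.null(fallback_table)) {
      opts <- pick(fallback_table, ft[i], "dante_average")
    }
    pw <- catalog$pack_weight_g[i]
    if (!is.null(pw) && !is.na(pw) && pw > 0 && pw <= max_pack_g) {
      opts <- dplyr::bind_rows(
        opts, tibble::tibble(label = "whole pack", grams = pw,
                             source = "pack"))
    }
    if (!is.null(opts) && nrow(opts) > 0) {
      out[[i]] <- dplyr::mutate(opts, item_id = catalog$item_id[i],
                                .before = 1)
    }
  }
  merged <- dplyr::bind_rows(
    existing,
    dplyr::bind_rows(purrr::compact(out)),
    per_item_portions)
  if (nrow(merged) == 0) {
    return(tibble::tibble(item_id = character(), label = character(),
                          grams = double(), source = character()))
  }
  stopifnot(all(merged$grams > 0))
  dplyr::distinct(merged, .data$item_id, .data$label, .keep_all = TRUE)
}

#' Attach portion-image keys to a catalog
#'
#' Food types covered by a portion-image atlas offer the user a choice of
#' exactly seven portion-size images; one image set may be shared by several
#' similar food types (the sliced-chicken images also serve other white
#' sliced meats). Only image keys are assigned here — assets live elsewhere.
#'
#' @param catalog Branded catalog tibble (`food_type` or `food_group`).
#' @param image_map Tibble (`food_type`, `image_key`), exactly seven rows
#'   per food type.
#' @return List: `assignments` (tibble `item_id`, `image_key`, `position`
#'   1-7) and `counts` (`items_with_images`, `distinct_image_keys`).
#' @export
attach_images <- function(catalog, image_map) {
  counts0 <- tibble::tibble(items_with_images = 0L, distinct_image_keys = 0L)
  if (is.null(image_map) || nrow(image_map) == 0) {
    return(list(assignments = tibble::tibble(item_id = character(),
                                             image_key = character(),
                                             position = integer()),
                counts = counts0))
  }
  per_type <- table(image_map$food_type)
  bad <- names(per_type)[per_type != 7]
  if (length(bad) > 0) {
    stop("food type(s) mapped to a number of image keys other than 7: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ft <- if ("food_type" %in% names(catalog)) {
    catalog$food_type
  } else {
    catalog$food_group
  }
  covered <- which(ft %in% unique(image_map$food_type))
  assignments <- dplyr::bind_rows(lapply(covered, function(i) {
    keys <- image_map$image_key[image_map$food_type == ft[i]]
    tibble::tibble(item_id = catalog$item_id[i], image_key = keys,
                   position = seq_along(keys))
  }))
  if (nrow(assignments) == 0) {
    assignments <- tibble::tibble(item_id = character(),
                                  image_key = character(),
                                  position = integer())
  }
  list(assignments = assignments,
       counts = tibble::tibble(
         items_with_images = length(covered),
         distinct_image_keys = length(unique(assignments$image_key))))
}
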