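#' Read a branded-item catalog
#'
#' Reads a comma-delimited branded catalog (one row per product) into a
#' tibble. Blank nutrient cells become `NA` — missing, never zero. Cells that
#' fail numeric coercion are blanked and collected in a reject table rather
#' than silently dropped, so a review queue can be built from them.
#'
#' Expected columns: `item_id`, `description`, `brand`, `barcode`,
#' `food_group`, the eight BOP nutrients (see [bop_nutrients()]), optionally
#' `salt_g`, `pack_weight_g`, `multipack_count`, `is_food`, `status`.
#' `item_id` and `description` are mandatory.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping expected column
#'   names to the file's header names (e.g. `c(item_id = "sku")`).
#' @return A tibble of items with attribute `rejects`: a tibble
#'   (`item_id`, `column`, `raw`) of cells that failed coercion.
#' @export
read_branded_catalog <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (!is.null(schema)) {
    for (want in names(schema)) {
      have <- schema[[want]]
      if (have %in% names(raw)) names(raw)[names(raw) == have] <- want
    }
  }
  missing_cols <- setdiff(c("item_id", "description"), names(raw))
  if (length(missing_cols) > 0) {
    stop("branded catalog is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dups <- unique(raw$item_id[duplicated(raw$item_id)])
  if (length(dups) > 0) {
    stop("duplicate item_id in branded catalog: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c(bop_nutrients(), "salt_g", "pack_weight_g", "multipack_count"),
    names(raw))
  coerced <- coerce_numeric_cols(raw, numeric_cols, raw$item_id)
  cat <- coerced$data
  if ("is_food" %in% names(cat)) {
    cat$is_food <- tolower(trimws(cat$is_food)) %in% c("true", "t", "1", "yes")
  } else {
    cat$is_food <- TRUE
  }
  if (!"status" %in% names(cat)) cat$status <- "active"
  cat$status[is.na(cat$status)] <- "active"
  attr(cat, "rejects") <- coerced$rejects
  cat
}

coerce_numeric_cols <- function(data, cols, ids) {
  rejects <- list()
  for (col in cols) {
    x <- data[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad)) {
      rejects[[col]] <- tibble::tibble(
        item_id = ids[bad], column = col, raw = x[bad])
    }
    data[[col]] <- num
  }
  rejects <- if (length(rejects) > 0) {
    dplyr::bind_rows(rejects)
  } else {
    tibble::tibble(item_id = character(), column = character(),
                   raw = character())
  }
  list(data = data, rejects = rejects)
}

#' Read a generic reference-food catalog
#'
#' Reads the reference catalog (one row per generic food code) carrying the
#' eight BOP macronutrients plus any registered micronutrient columns.
#' Generic rows missing any of the four ranking macronutrients (energy, fat,
#' protein, carbohydrate) cannot take part in mapping and are moved to the
#' reject table.
#'
#' @param path CSV file path with columns `code`, `description`,
#'   `food_group`, the macros, then one column per micronutrient key.
#' @param registry A [nutrient_registry()] declaring the unit per key;
#'   file columns not in the registry and not structural raise a warning.
#' @return Tibble of usable generic foods, with attribute `rejects` holding
#'   rows that lack a ranking macronutrient.
#' @export
read_generic_catalog <- function(path, registry = nutrient_registry()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  stopifnot(all(c("code", "description") %in% names(raw)))
  dups <- unique(raw$code[duplicated(raw$code)])
  if (length(dups) > 0) {
    stop("duplicate code in generic catalog: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  structural <- c("code", "description", "food_group", "food_type")
  unknown <- setdiff(names(raw), c(structural, registry$key, "salt_g"))
  if (length(unknown) > 0) {
    warning("generic catalog has unregistered column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(c(registry$key, "salt_g"), names(raw))
  cat <- coerce_numeric_cols(raw, numeric_cols, raw$code)$data
  ranking <- c("energy_kcal", "fat_g", "protein_g", "carb_g")
  have <- intersect(ranking, names(cat))
  complete <- rowSums(is.na(cat[have])) == 0 & length(have) == 4
  rejected <- cat[!complete, , drop = FALSE]
  cat <- cat[complete, , drop = FALSE]
  attr(cat, "rejects") <- rejected
  cat
}

#' Write (and re-read) QC or mapping reports
#'
#' Round-trip stable serialization of flag or mapping tables: numbers are
#' written at four decimal places, one JSON object per line for `jsonl`, a
#' header-only file for empty input.
#'
#' @param x Tibble (QC flags, mapping results, suggestions, ...).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  x <- tibble::as_tibble(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) round(v, 4))
  if (format == "csv") {
    readr::write_csv(x, path, na = "")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (nrow(x) > 0) {
      for (i in seq_len(nrow(x))) {
        rec <- as.list(x[i, ])
        rec <- rec[!vapply(rec, function(v) is.na(v)[1], logical(1))]
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_report
#' @param col_types Optional readr column specification for CSV input.
#' @export
read_report <- function(path, format = c("csv", "jsonl"), col_types = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, na = "", progress = FALSE, show_col_types = FALSE,
                    col_types = col_types)
  } else {
    lines <- readLines(path)
    if (length(lines) == 0) return(tibble::tibble())
    dplyr::bind_rows(lapply(lines, function(l) {
      tibble::as_tibble(jsonlite::fromJSON(l))
    }))
  }
}

#' Read a cleaning / simulation rule file
#'
#' Thin wrapper over [yaml::read_yaml()] so rule sets and simulation configs
#' can live in version-controlled key-value files.
#'
#' @param path YAML (or JSON, which YAML subsumes) file path.
#' @return Named list.
#' @export
read_rules <- function(path) yaml::read_yaml(path)
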