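# Historical dosage units and standardized dosage vectors.
#
# Prescriptions from historical Chinese materia medica record drug masses in
# dynastic units (Fen, Qian, Liang) whose metric value depends on the era.
# This module converts them to grams and standardizes a prescription's
# dosages to a ratio vector whose minimum component is exactly 1 -- the
# object every downstream network weight is derived from.

#' Load the dynastic unit conversion table
#'
#' Reads the versioned YAML conversion config shipped with the package (or a
#' user-supplied extension of it) and expands it into a tidy lookup table.
#' One Liang equals 10 Qian equals 100 Fen in both dynastic systems; the
#' gram value of one Fen differs (0.4 g Song-Yuan, 0.37 g Ming-Qing). The
#' modern unit `"gram"` is included as a pass-through so present-day
#' prescriptions can be analyzed alongside historical ones.
#'
#' @param path Optional path to a YAML config with fields `grams_per_fen`
#'   (named list dynasty -> grams) and `fen_per_unit` (named list
#'   unit -> Fen equivalents). Defaults to the table shipped with the
#'   package.
#'
#' @return A tibble with columns `unit`, `dynasty` and `grams_per_unit`.
#'   The config `version` is attached as an attribute.
#' @export
#' @examples
#' unit_conversion_table()
unit_conversion_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "unit_conversions.yaml",
      package = "dosenet", mustWork = TRUE
    )
  cfg <- yaml::read_yaml(path)
  dynasties <- names(cfg$grams_per_fen)
  units <- names(cfg$fen_per_unit)
  tbl <- tidyr::expand_grid(unit = units, dynasty = dynasties)
  tbl$grams_per_unit <- purrr::map2_dbl(
    tbl$unit, tbl$dynasty,
    function(u, d) cfg$fen_per_unit[[u]] * cfg$grams_per_fen[[d]]
  )
  out <- dplyr::bind_rows(
    tbl,
    tibble::tibble(unit = "gram", dynasty = dynasties, grams_per_unit = 1)
  )
  attr(out, "version") <- cfg$version
  out
}

#' Convert dosage records to grams
#'
#' Converts each record's `(quantity, unit, dynasty)` triple to a mass in
#' grams via the conversion table: grams = quantity x Fen-equivalents of the
#' unit x grams-per-Fen of the dynasty. Gram-unit records pass through
#' unchanged. Non-quantifiable units (e.g. "grains", "handful") are rejected
#' with an error naming the offending unit rather than coerced.
#'
#' @param records Data frame of dosage records with columns `drug_id`,
#'   `quantity` (positive real), `unit` and `dynasty`.
#' @param conversion Conversion table, as from [unit_conversion_table()].
#'
#' @return The input as a tibble with an added `grams` column.
#' @export
#' @examples
#' convert_to_grams(tibble::tibble(
#'   drug_id = "XiongHuang", quantity = 1, unit = "Qian", dynasty = "SongYuan"
#' ))
convert_to_grams <- function(records, conversion = unit_conversion_table()) {
  assert_columns(records, c("drug_id", "quantity", "unit", "dynasty"),
    what = "prescription"
  )
  records <- tibble::as_tibble(records)
  if (!is.numeric(records$quantity) ||
    any(!is.finite(records$quantity)) ||
    any(records$quantity <= 0)) {
    abort_validation("all quantities must be finite positive numbers")
  }
  bad_units <- setdiff(unique(records$unit), unique(conversion$unit))
  if (length(bad_units) > 0) {
    abort_validation(sprintf(
      "non-quantifiable or unknown unit(s): %s",
      paste(sprintf("'%s'", bad_units), collapse = ", ")
    ))
  }
  bad_dyn <- setdiff(unique(records$dynasty), unique(conversion$dynasty))
  if (length(bad_dyn) > 0) {
    abort_validation(sprintf(
      "unknown dynasty value(s): %s",
      paste(sprintf("'%s'", bad_dyn), collapse = ", ")
    ))
  }
  out <- dplyr::left_join(records, conversion, by = c("unit", "dynasty"))
  out$grams <- out$quantity * out$grams_per_unit
  dplyr::select(out, -"grams_per_unit")
}

new_dosage_vector <- function(drug_id, value, grams = NULL) {
  out <- tibble::tibble(drug_id = as.character(drug_id))
  if (!is.null(grams)) out$grams <- as.numeric(grams)
  out$value <- as.numeric(value)
  class(out) <- c("dosage_vector", class(out))
  out
}

#' Construct a standardized dosage vector
#'
#' A standardized dosage vector carries one dimensionless weight per drug,
#' obtained by dividing each gram dosage by the prescription minimum, so
#' that `min(value) == 1`. It is the per-drug edge weight of the
#' dosage-weighted network; the all-ones vector plays the same role for the
#' non-dosage network.
#'
#' @param drug_ids Character vector of drug identifiers (no duplicates).
#' @param values Positive numeric dosages, in any common unit.
#' @param standardize If `TRUE` (default) divide by the minimum so the
#'   invariant `min(value) == 1` holds; if `FALSE` the values are taken as
#'   given (arbitrary positive weights).
#'
#' @return A `dosage_vector`: a tibble with columns `drug_id` and `value`.
#' @export
#' @examples
#' dosage_vector(c("a", "b", "c"), c(0.4, 0.4, 4))
dosage_vector <- function(drug_ids, values, standardize = TRUE) {
  drug_ids <- as.character(drug_ids)
  values <- as.numeric(values)
  if (length(drug_ids) != length(values)) {
    abort_validation("drug_ids and values must have the same length")
  }
  if (length(values) < 1) abort_validation("dosage vector must be non-empty")
  if (anyDuplicated(drug_ids) > 0) {
    abort_validation("duplicated drug_id in dosage vector")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort_validation("all dosage values must be finite and positive")
  }
  if (standardize) values <- values / min(values)
  new_dosage_vector(drug_ids, values)
}

#' Standardize a prescription's dosages
#'
#' Converts all records to grams and divides by the minimum gram dosage,
#' yielding the standardized dosage vector (minimum component exactly 1).
#' Mixed units within one prescription are allowed; mixed dynasties are
#' rejected because the two conversion systems are incompatible.
#'
#' @inheritParams convert_to_grams
#'
#' @return A `dosage_vector` tibble with columns `drug_id`, `grams`, `value`.
#' @export
#' @examples
#' standardize_dosage(chong_he_fixture()$records)
standardize_dosage <- function(records, conversion = unit_conversion_table()) {
  if (nrow(records) < 1) {
    abort_validation("prescription must contain at least one record")
  }
  if (anyDuplicated(records$drug_id) > 0) {
    abort_validation("duplicated drug_id in prescription")
  }
  if (length(unique(records$dynasty)) > 1) {
    abort_validation(
      "mixed dynasties within one prescription are not supported"
    )
  }
  conv <- convert_to_grams(records, conversion)
  new_dosage_vector(conv$drug_id, conv$grams / min(conv$grams),
    grams = conv$grams
  )
}

#' All-ones dosage vector
#'
#' The standardized dosage vector of the non-dosage network variant: every
#' drug weighted 1.
#'
#' @param n Number of drugs (positive integer); ignored when `drug_ids` is
#'   given.
#' @param drug_ids Optional drug identifiers; defaults to `drug1..drugn`.
#'
#' @return A `dosage_vector` of ones.
#' @export
#' @examples
#' ones_vector(3)
ones_vector <- function(n = length(drug_ids), drug_ids = NULL) {
  if (is.null(drug_ids)) {
    if (length(n) != 1 || !is.finite(n) || n < 1 || n != as.integer(n)) {
      abort_validation("n must be a positive integer")
    }
    drug_ids <- paste0("drug", seq_len(n))
  }
  dosage_vector(drug_ids, rep(1, length(drug_ids)), standardize = FALSE)
}

# numeric weights from a dosage_vector / data frame / bare numeric
dosage_values <- function(x) {
  if (is.data.frame(x)) {
    col <- if ("value" %in% names(x)) "value" else stop("no value column")
    as.numeric(x[[col]])
  } else {
    as.numeric(x)
  }
}

#' Validate a prescription against the filtering rules
#'
#' Applies the two exclusion rules used when curating historical
#' prescriptions: (1) every record must use a quantifiable mass unit from
#' the conversion table ("50 grains of glutinous rice" style dosages are
#' rejected, not modeled); (2) when a component map is supplied, every drug
#' must have at least one bioactive metabolite with at least one known
#' target. Returns a structured report rather than throwing.
#'
#' @inheritParams convert_to_grams
#' @param maps Optional [component_map()] used to check metabolite/target
#'   coverage.
#'
#' @return A `prescription_validation` tibble with columns `drug_id`,
#'   `valid`, `reason`, plus attributes `valid` (overall pass/fail) and
#'   `issues` (prescription-level problems such as mixed dynasties).
#' @export
#' @examples
#' fx <- chong_he_fixture()
#' validate_prescription(fx$records, fx$maps)
validate_prescription <- function(records, maps = NULL,
                                  conversion = unit_conversion_table()) {
  assert_columns(records, c("drug_id", "quantity", "unit", "dynasty"),
    what = "prescription"
  )
  records <- tibble::as_tibble(records)
  issues <- character()
  if (nrow(records) == 0) issues <- c(issues, "prescription is empty")
  if (length(unique(records$dynasty)) > 1) {
    issues <- c(issues, "mixed dynasties within one prescription")
  }
  if (anyDuplicated(records$drug_id) > 0) {
    issues <- c(issues, "duplicated drug_id")
  }

  known_units <- unique(conversion$unit)
  known_dyn <- unique(conversion$dynasty)
  covered <- NULL
  if (!is.null(maps)) {
    mt <- maps$metabolite_target
    dm <- maps$drug_metabolite
    with_target <- unique(mt$metabolite_id[!is.na(mt$gene_symbol)])
    covered <- unique(dm$drug_id[dm$metabolite_id %in% with_target])
  }

  reason <- purrr::pmap_chr(
    list(records$drug_id, records$quantity, records$unit, records$dynasty),
    function(drug, qty, unit, dyn) {
      probs <- character()
      if (!is.finite(qty) || qty <= 0) {
        probs <- c(probs, "non-positive quantity")
      }
      if (!unit %in% known_units) {
        probs <- c(probs, sprintf("non-quantifiable unit '%s'", unit))
      }
      if (!dyn %in% known_dyn) {
        probs <- c(probs, sprintf("unknown dynasty '%s'", dyn))
      }
      if (!is.null(covered) && !drug %in% covered) {
        probs <- c(probs, "no metabolite/target data")
      }
      if (length(probs) == 0) NA_character_ else paste(probs, collapse = "; ")
    }
  )

  out <- tibble::tibble(
    drug_id = records$drug_id,
    valid = is.na(reason),
    reason = reason
  )
  attr(out, "issues") <- issues
  attr(out, "valid") <- all(out$valid) && length(issues) == 0
  class(out) <- c("prescription_validation", class(out))
  out
}

#' Did a prescription pass validation?
#'
#' @param x A `prescription_validation` report from [validate_prescription()].
#' @return Logical scalar.
#' @export
is_valid <- function(x) {
  isTRUE(attr(x, "valid"))
}

#' @export
print.prescription_validation <- function(x, ...) {
  status <- if (is_valid(x)) "PASS" else "FAIL"
  cat(sprintf("<prescription validation: %s>\n", status))
  issues <- attr(x, "issues")
  if (length(issues) > 0) {
    cat(paste0("  ! ", issues, collapse = "\n"), "\n")
  }
  NextMethod()
}

#' Read a prescription table from CSV or JSON
#'
#' @param path File path; format chosen by extension (`.json` vs anything
#'   else, read as CSV). Required columns: `drug_id`, `quantity`, `unit`,
#'   `dynasty`.
#'
#' @return A tibble of dosage records.
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("prescription file not found: %s", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  assert_columns(df, c("drug_id", "quantity", "unit", "dynasty"),
    what = sprintf("prescription file '%s'", path)
  )
  df$drug_id <- as.character(df$drug_id)
  df$quantity <- as.numeric(df$quantity)
  df
}
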