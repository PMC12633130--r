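# Cohort container, validation and CSV I/O.
#
# A cohort is a plain tibble: a `patient_id` column plus one column per
# schema feature, in schema order. Categorical features are stored as
# character labels (not integer codes), numerical features as doubles.
# Missingness — random or structural — is carried as NA; the boolean missing
# mask of the design is therefore `is.na()` of the value table, and CSV
# round-trips map the empty cell to NA and back.

#' Assemble a cohort tibble
#'
#' @param values A data frame of feature columns (schema subset).
#' @param patient_id Optional identifier vector; generated when absent.
#' @return A tibble with `patient_id` first.
#' @export
as_cohort <- function(values, patient_id = NULL) {
  values <- tibble::as_tibble(values)
  if ("patient_id" %in% names(values)) {
    return(dplyr::relocate(values, "patient_id"))
  }
  patient_id <- patient_id %||% patient_ids(nrow(values))
  dplyr::bind_cols(tibble::tibble(patient_id = patient_id), values)
}

cohort_feature_names <- function(cohort) setdiff(names(cohort), "patient_id")

#' Validate a cohort against a schema
#'
#' Checks every schema invariant cell-wise: categorical values must be
#' declared categories, bounded numerical values must lie within bounds,
#' and structurally-gated features (post-surgical pathology, radiotherapy
#' parameters) must be missing whenever their gate condition fails. Columns
#' not declared in the schema are a hard error.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param schema A `twin_schema`.
#' @return A `twin_validation` tibble of violations with columns
#'   `feature`, `patient_id`, `type`, `message`; zero rows iff valid.
#' @export
#' @examples
#' cohort <- generate_cohort(default_params(), n = 20, seed = 1)$cohort
#' nrow(validate_cohort(cohort, default_schema())) == 0
validate_cohort <- function(cohort, schema) {
  feats <- cohort_feature_names(cohort)
  unknown <- setdiff(feats, schema$name)
  if (length(unknown)) {
    stop_hnc("cohort has column(s) not declared in schema: %s",
             paste(unknown, collapse = ", "))
  }
  ids <- if ("patient_id" %in% names(cohort)) cohort$patient_id else patient_ids(nrow(cohort))

  violations <- list()
  note <- function(feature, patient_id, type, message) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(
      feature = feature, patient_id = patient_id, type = type, message = message
    )
  }

  for (f in feats) {
    row <- schema_row(schema, f)
    x <- cohort[[f]]
    obs <- !is.na(x)
    if (row$kind == "categorical") {
      bad <- obs & !(x %in% row$categories[[1]])
      for (i in which(bad)) {
        note(f, ids[i], "category",
             sprintf("value '%s' is not a declared category of %s", x[i], f))
      }
    } else {
      if (!is.numeric(x)) {
        note(f, NA_character_, "type", sprintf("column %s is not numeric", f))
        next
      }
      if (!is.na(row$lo) && !is.na(row$hi)) {
        bad <- obs & (x < row$lo | x > row$hi)
        for (i in which(bad)) {
          note(f, ids[i], "bounds",
               sprintf("value %g of %s outside [%g, %g]", x[i], f, row$lo, row$hi))
        }
      }
    }
    # structural gating: value present while the gate condition fails
    if (row$missing_policy == "structural" && row$condition_feature %in% feats) {
      allowed <- strsplit(row$condition_value, "|", fixed = TRUE)[[1]]
      gate <- cohort[[row$condition_feature]]
      bad <- obs & (is.na(gate) | !(gate %in% allowed))
      for (i in which(bad)) {
        note(f, ids[i], "structural",
             sprintf("%s observed although %s is not in {%s}",
                     f, row$condition_feature, paste(allowed, collapse = ", ")))
      }
    }
  }

  out <- if (length(violations)) dplyr::bind_rows(violations) else
    tibble::tibble(feature = character(), patient_id = character(),
                   type = character(), message = character())
  class(out) <- c("twin_validation", class(out))
  out
}

#' Write / read a cohort as CSV
#'
#' UTF-8 comma-separated files with a header row of feature names; the
#' empty cell encodes a missing value. Categorical values are stored as
#' labels. `read_cohort()` accepts the cleaned header aliases of
#' [schema_alias_map()] and restores canonical names; columns absent from
#' the schema are an error, as is a non-numeric cell in a numerical column
#' (reported with its row and column).
#'
#' @param cohort A cohort tibble.
#' @param path CSV file path.
#' @param schema A `twin_schema`.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a cohort
#'   tibble typed per the schema (round-trip identity with the mask).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  # empty string = missing
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(),
                                          ~ dplyr::if_else(.x == "", NA_character_, .x)))
  # restore canonical names from aliases
  amap <- schema_alias_map()
  hit <- match(names(raw), amap$alias)
  names(raw)[!is.na(hit)] <- amap$name[stats::na.omit(hit)]

  feats <- setdiff(names(raw), "patient_id")
  unknown <- setdiff(feats, schema$name)
  if (length(unknown)) {
    stop_hnc("CSV has column(s) not in schema: %s", paste(unknown, collapse = ", "))
  }
  for (f in feats) {
    row <- schema_row(schema, f)
    if (row$kind == "numerical") {
      x <- raw[[f]]
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(parsed))
      if (length(bad)) {
        stop_hnc("unparseable numeric cell '%s' at row %d, column '%s'",
                 x[bad[1]], bad[1], f)
      }
      raw[[f]] <- parsed
    }
  }
  as_cohort(raw)
}
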