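# Feature schema for the five variable groups of the treatment model:
#   PTF  pre-treatment features (demographics, staging, baseline symptoms)
#   ACTIONS first-cycle treatment actions (surgery, induction, radiotherapy)
#   PIO  post-intervention outcomes (pathology, radiotherapy parameters)
#   PRS  patient-reported MDASI-HN symptom scores at four assessments
#   TPO  treatment-plan outcome (three-year relapse)

FEATURE_GROUPS <- c("PTF", "ACTIONS", "PIO", "PRS", "TPO")
SYMPTOMS <- c("fatigue", "drymouth", "swallow", "taste")
PRS_PHASES <- c("endrt", "wk6", "m3", "m12")

ACTION_LABELS <- list(
  definitive = c("no", "yes"),
  induction = c("no", "yes"),
  `radio/chemo` = c("no", "yes", "yes_with_concurrent_chemotherapy")
)

# Map the action labels as printed in the demographic tables onto the clean
# category labels used throughout the package.
printed_action_label <- c(
  "No" = "no", "Yes" = "yes",
  "0 No" = "no", "1 Yes" = "yes",
  "2 Yes with concurrent chemo?" = "yes_with_concurrent_chemotherapy"
)

new_schema_row <- function(name, group, kind, categories = NULL, mean = NA_real_,
                           sd = NA_real_, lo = NA_real_, hi = NA_real_,
                           integer_valued = FALSE, dist = NA_character_,
                           missing_policy = "never", condition_feature = NA_character_,
                           condition_value = NA_character_) {
  tibble::tibble(
    name = name, group = group, kind = kind,
    categories = list(categories), mean = mean, sd = sd, lo = lo, hi = hi,
    integer_valued = integer_valued, dist = dist,
    missing_policy = missing_policy,
    condition_feature = condition_feature, condition_value = condition_value
  )
}

#' Default feature schema of the treatment digital twin
#'
#' Builds the registry of every modelled variable: its feature group, type
#' (categorical with ordered labels, or numerical with mean/sd and optional
#' bounds), and missingness policy. Categorical category sets and numerical
#' moments come from the published cohort tables (see
#' [cohort_demographics()], [cohort_moments()]). Post-surgical pathology
#' (`ENE`, `Margin`) is structurally missing unless `definitive == "yes"`;
#' radiotherapy parameters (`rt_type`, `rt_dose`, `rt_fraction`) are
#' structurally missing unless radiotherapy was given; `relapse_yr3` is
#' observed for a random labelled subset.
#'
#' Variable names keep the source tables' verbatim spellings (including
#' `status_at_enrollememt` and `p16_hpv_postive`) so published rows stay
#' traceable; [schema_alias_map()] provides clean aliases accepted at I/O.
#'
#' @return A `twin_schema` tibble, one row per feature, in chain
#'   (chronological) order.
#' @export
#' @examples
#' sch <- default_schema()
#' dplyr::count(sch, group)
default_schema <- function() {
  demo <- cohort_demographics()
  mom <- cohort_moments()
  cats <- function(v) demo$category[demo$variable == v]
  mo <- function(v) {
    r <- mom[mom$variable == v, ]
    if (!nrow(r)) stop_hnc("no printed moments for '%s'", v)
    c(r$mean, r$sd)
  }

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- new_schema_row(...)

  # ---- PTF ----------------------------------------------------------------
  add("age", "PTF", "numerical", mean = mo("age")[1], sd = mo("age")[2], dist = "normal")
  add("gender", "PTF", "categorical", categories = cats("gender"))
  add("ethnicity", "PTF", "categorical", categories = cats("ethnicity"))
  add("race", "PTF", "categorical", categories = cats("race"))
  # smoking_status codes are opaque categorical labels (no ordinal meaning)
  add("smoking_status", "PTF", "categorical", categories = cats("smoking_status"))
  for (v in c("tobacco_packs_per_day", "tobacco_used_years", "pack_years")) {
    m <- mo(v)
    add(v, "PTF", "numerical", mean = m[1], sd = m[2], dist = "lognormal")
  }
  add("site_of_tumor", "PTF", "categorical", categories = cats("site_of_tumor"))
  add("ajcc_version", "PTF", "categorical", categories = cats("ajcc_version"))
  add("p16_hpv_postive", "PTF", "categorical", categories = cats("p16_hpv_postive"))
  add("tumor_laterality", "PTF", "categorical", categories = cats("tumor_laterality"))
  add("t_nominal", "PTF", "categorical", categories = cats("t_nominal"))
  add("n_nominal", "PTF", "categorical", categories = cats("n_nominal"))
  add("m", "PTF", "categorical", categories = cats("m"))
  add("status_at_enrollememt", "PTF", "categorical", categories = cats("status_at_enrollememt"))
  for (s in SYMPTOMS) {
    v <- paste0("mdasi_baseline_", s)
    m <- mo(v)
    add(v, "PTF", "numerical", mean = m[1], sd = m[2], lo = 0, hi = 10,
        integer_valued = TRUE, dist = "normal")
  }

  # ---- ACTIONS ------------------------------------------------------------
  add("definitive", "ACTIONS", "categorical", categories = ACTION_LABELS$definitive)
  # ENE / Margin are surgical pathology: only observed after definitive surgery
  add("ENE", "PIO", "categorical", categories = c("Positive", "Negative"),
      missing_policy = "structural", condition_feature = "definitive",
      condition_value = "yes")
  add("Margin", "PIO", "categorical", categories = cats("Margin"),
      missing_policy = "structural", condition_feature = "definitive",
      condition_value = "yes")
  add("induction", "ACTIONS", "categorical", categories = ACTION_LABELS$induction)
  add("radio/chemo", "ACTIONS", "categorical", categories = ACTION_LABELS$`radio/chemo`)

  # ---- PIO (radiotherapy parameters) --------------------------------------
  rt_cond <- "yes|yes_with_concurrent_chemotherapy"
  add("rt_type", "PIO", "categorical", categories = cats("rt_type"),
      missing_policy = "structural", condition_feature = "radio/chemo",
      condition_value = rt_cond)
  m <- mo("rt_dose")
  add("rt_dose", "PIO", "numerical", mean = m[1], sd = m[2], dist = "normal",
      missing_policy = "structural", condition_feature = "radio/chemo",
      condition_value = rt_cond)
  m <- mo("rt_fraction")
  add("rt_fraction", "PIO", "numerical", mean = m[1], sd = m[2],
      integer_valued = TRUE, dist = "normal",
      missing_policy = "structural", condition_feature = "radio/chemo",
      condition_value = rt_cond)

  # ---- PRS ----------------------------------------------------------------
  for (ph in PRS_PHASES) {
    for (s in SYMPTOMS) {
      v <- paste0("mdasi_", ph, "_", s)
      m <- mo(v)
      add(v, "PRS", "numerical", mean = m[1], sd = m[2], lo = 0, hi = 10,
          integer_valued = TRUE, dist = "normal", missing_policy = "random")
    }
  }

  # ---- TPO ----------------------------------------------------------------
  add("relapse_yr3", "TPO", "categorical", categories = c("False", "True"),
      missing_policy = "random")

  schema <- dplyr::bind_rows(rows)
  class(schema) <- c("twin_schema", class(schema))
  assert_schema(schema)
  schema
}

# Schema invariants: unique names, one group each, categorical specs have
# >= 2 categories and no moments, numerical specs have moments and no
# categories, bounds satisfy lo < hi.
assert_schema <- function(schema) {
  if (anyDuplicated(schema$name)) stop_hnc("duplicate feature names in schema")
  if (!all(schema$group %in% FEATURE_GROUPS)) stop_hnc("unknown feature group")
  for (i in seq_len(nrow(schema))) {
    row <- schema[i, ]
    cs <- row$categories[[1]]
    if (row$kind == "categorical") {
      if (length(cs) < 2) stop_hnc("categorical feature '%s' needs >= 2 categories", row$name)
      if (!is.na(row$mean) || !is.na(row$sd)) {
        stop_hnc("categorical feature '%s' must not carry moments", row$name)
      }
    } else if (row$kind == "numerical") {
      if (!is.null(cs)) stop_hnc("numerical feature '%s' must not carry categories", row$name)
      if (is.na(row$mean) || is.na(row$sd) || row$sd < 0) {
        stop_hnc("numerical feature '%s' needs mean and sd >= 0", row$name)
      }
      if (!is.na(row$lo) && !is.na(row$hi) && row$lo >= row$hi) {
        stop_hnc("feature '%s': bounds must satisfy lo < hi", row$name)
      }
    } else {
      stop_hnc("feature '%s': unknown kind '%s'", row$name, row$kind)
    }
  }
  invisible(schema)
}

schema_features <- function(schema, groups = NULL, kind = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(groups)) keep <- keep & schema$group %in% groups
  if (!is.null(kind)) keep <- keep & schema$kind %in% kind
  schema$name[keep]
}

schema_row <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) stop_hnc("unknown feature '%s'", name)
  schema[i, ]
}

schema_categories <- function(schema, name) schema_row(schema, name)$categories[[1]]

# Is this feature structurally observed for a given record (named list /
# one-row data frame)? Returns TRUE for features with no structural rule.
structurally_observed <- function(schema, name, record) {
  row <- schema_row(schema, name)
  if (row$missing_policy != "structural") return(TRUE)
  cond_val <- record[[row$condition_feature]]
  if (is.null(cond_val) || is.na(cond_val)) return(FALSE)
  cond_val %in% strsplit(row$condition_value, "|", fixed = TRUE)[[1]]
}

#' Alias map between verbatim and cleaned feature names
#'
#' The schema keeps the source tables' verbatim spellings; this map links
#' them to cleaned aliases (`status_at_enrollment`, `p16_hpv_positive`,
#' `radio_chemo`) which [read_cohort()] accepts in CSV headers.
#'
#' @return A tibble with columns `name` (canonical) and `alias`.
#' @export
schema_alias_map <- function() {
  tibble::tibble(
    name = c("status_at_enrollememt", "p16_hpv_postive", "radio/chemo"),
    alias = c("status_at_enrollment", "p16_hpv_positive", "radio_chemo")
  )
}

#' Serialise / restore a schema as JSON
#'
#' @param schema A `twin_schema`.
#' @param path File path to write to / read from.
#' @return `write_schema_json()` returns `path` invisibly;
#'   `read_schema_json()` returns a `twin_schema`.
#' @export
write_schema_json <- function(schema, path) {
  out <- purrr::map(seq_len(nrow(schema)), function(i) {
    row <- as.list(schema[i, ])
    row$categories <- schema$categories[[i]]
    row
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  raw <- jsonlite::read_json(path)
  rows <- purrr::map(raw, function(r) {
    new_schema_row(
      name = r$name, group = r$group, kind = r$kind,
      categories = if (length(r$categories)) unlist(r$categories) else NULL,
      mean = r$mean %||% NA_real_, sd = r$sd %||% NA_real_,
      lo = r$lo %||% NA_real_, hi = r$hi %||% NA_real_,
      integer_valued = isTRUE(r$integer_valued), dist = r$dist %||% NA_character_,
      missing_policy = r$missing_policy %||% "never",
      condition_feature = r$condition_feature %||% NA_character_,
      condition_value = r$condition_value %||% NA_character_
    )
  })
  schema <- dplyr::bind_rows(rows)
  class(schema) <- c("twin_schema", class(schema))
  assert_schema(schema)
}
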