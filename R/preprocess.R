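# Preprocessing: per-feature z-scoring with invertible transforms fitted on
# training data only, family-specific missing-value imputation, and the
# seed-reproducible train/test split.

#' Fit a per-feature normalizer on training data
#'
#' Computes (mean, sd) for every numerical feature present in `train`,
#' using the population (divide-by-n) standard-deviation convention.
#' Constant features are passed through unscaled (sd treated as 1) and
#' flagged. Fitted on training rows only, so no test-set statistic can
#' leak into the transform.
#'
#' @param train Training cohort tibble.
#' @param schema A `twin_schema`.
#' @return A `twin_normalizer`: tibble with `feature`, `mean`, `sd`,
#'   `constant`.
#' @export
#' @examples
#' gen <- generate_cohort(default_params(), 50, seed = 1)
#' norm <- fit_normalizer(gen$cohort, default_schema())
fit_normalizer <- function(train, schema) {
  feats <- intersect(cohort_feature_names(train),
                     schema_features(schema, kind = "numerical"))
  rows <- purrr::map(feats, function(f) {
    x <- train[[f]][!is.na(train[[f]])]
    if (!length(x)) stop_hnc("cannot fit normalizer: column '%s' is all-missing", f)
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # population convention
    constant <- s == 0
    if (constant) {
      warn_hnc("constant column '%s' passed through unscaled", f)
      s <- 1
    }
    tibble::tibble(feature = f, mean = m, sd = s, constant = constant)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("twin_normalizer", class(out))
  out
}

#' Apply or invert a fitted normalizer
#'
#' `apply_normalizer()` z-scores every fitted column present in `cohort`;
#' `invert_normalizer()` restores the original scale. The two compose to
#' the identity to floating-point precision.
#'
#' @param cohort A cohort tibble.
#' @param normalizer A `twin_normalizer` from [fit_normalizer()].
#' @return The transformed cohort tibble.
#' @export
apply_normalizer <- function(cohort, normalizer) {
  for (i in seq_len(nrow(normalizer))) {
    f <- normalizer$feature[i]
    if (f %in% names(cohort)) {
      cohort[[f]] <- (cohort[[f]] - normalizer$mean[i]) / normalizer$sd[i]
    }
  }
  cohort
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(cohort, normalizer) {
  for (i in seq_len(nrow(normalizer))) {
    f <- normalizer$feature[i]
    if (f %in% names(cohort)) {
      cohort[[f]] <- cohort[[f]] * normalizer$sd[i] + normalizer$mean[i]
    }
  }
  cohort
}

# Normalize / denormalize a single numeric vector by feature name.
normalize_vec <- function(x, normalizer, feature) {
  i <- match(feature, normalizer$feature)
  if (is.na(i)) return(x)
  (x - normalizer$mean[i]) / normalizer$sd[i]
}

denormalize_vec <- function(x, normalizer, feature) {
  i <- match(feature, normalizer$feature)
  if (is.na(i)) return(x)
  x * normalizer$sd[i] + normalizer$mean[i]
}

#' Family-specific missing-value imputation
#'
#' For the `vae_mlp` family, numerical missing values are filled with the
#' training mean and categorical missing values with the most frequent
#' training category (ties broken by schema category order). The `boosted`
#' family returns the cohort unchanged: gradient-boosted trees consume
#' missing values natively. Imputation statistics are always computed on
#' `train` (defaulting to `cohort` itself when fitting), never on the data
#' being transformed.
#'
#' @param cohort Cohort tibble to impute.
#' @param schema A `twin_schema`.
#' @param family `"vae_mlp"` or `"boosted"`.
#' @param train Cohort supplying the imputation statistics.
#' @return The imputed cohort tibble.
#' @export
impute_cohort <- function(cohort, schema, family = c("vae_mlp", "boosted"),
                          train = cohort) {
  family <- match.arg(family)
  if (family == "boosted") return(cohort)
  for (f in cohort_feature_names(cohort)) {
    x <- cohort[[f]]
    if (!anyNA(x)) next
    row <- schema_row(schema, f)
    tx <- train[[f]][!is.na(train[[f]])]
    if (!length(tx)) next  # nothing to impute from (e.g. fully masked column)
    fill <- if (row$kind == "numerical") {
      mean(tx)
    } else {
      cats <- row$categories[[1]]
      tab <- table(factor(tx, levels = cats))
      cats[which.max(tab)]
    }
    x[is.na(x)] <- fill
    cohort[[f]] <- x
  }
  cohort
}

#' Random train/test split
#'
#' Disjoint, exhaustive, seed-reproducible random partition of the cohort
#' into `n_train` and `n_test` rows (defaults: the reference 539/137 split
#' when the cohort has 676 rows, otherwise an 80/20 split).
#'
#' @param cohort Cohort tibble.
#' @param n_train,n_test Partition sizes; must sum to `nrow(cohort)`.
#' @param seed Integer seed.
#' @return A list with cohort tibbles `train` and `test`.
#' @export
#' @examples
#' gen <- generate_cohort(default_params(), 676, seed = 1)
#' sp <- split_cohort(gen$cohort, seed = 7)
#' c(nrow(sp$train), nrow(sp$test))
split_cohort <- function(cohort, n_train = NULL, n_test = NULL, seed = NULL) {
  n <- nrow(cohort)
  if (is.null(n_train)) n_train <- if (n == 676) 539L else round(0.8 * n)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test != n) {
    stop_hnc("n_train + n_test (%d) must equal cohort size (%d)", n_train + n_test, n)
  }
  with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train = cohort[sort(idx), ], test = cohort[sort(setdiff(seq_len(n), idx)), ])
  })
}
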