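# Fidelity and predictive-performance metrics: per-feature order-1
# Wasserstein distance between real and synthetic cohorts (total-variation
# distance for categorical features, the W1 analogue under the 0/1 ground
# metric), macro-F1 and MSE, and the benchmark table comparing the boosted
# chain with the median/mean, random, and MLP baselines.

#' Order-1 Wasserstein distance between two empirical distributions
#'
#' Computed exactly as the integral of the absolute difference of the two
#' empirical CDFs.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (NAs dropped).
#' @return A non-negative scalar.
#' @export
#' @examples
#' wasserstein_1d(c(0, 1), c(0, 1, 1))  # 1/6
wasserstein_1d <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop_hnc("wasserstein_1d: empty sample")
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1) return(0)
  Fa <- stats::ecdf(a)(xs[-length(xs)])
  Fb <- stats::ecdf(b)(xs[-length(xs)])
  sum(abs(Fa - Fb) * diff(xs))
}

#' Total-variation distance between categorical samples
#'
#' `0.5 * sum |p - q|` over the declared categories — the Wasserstein-1
#' distance under the 0/1 ground metric, used so categorical features can
#' enter the fidelity average.
#'
#' @param sample_a,sample_b Character vectors (NAs dropped).
#' @param categories Declared category set (default: union of observed).
#' @return A scalar in `[0, 1]`.
#' @export
categorical_distance <- function(sample_a, sample_b, categories = NULL) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop_hnc("categorical_distance: empty sample")
  categories <- categories %||% sort(unique(c(a, b)))
  p <- table(factor(a, levels = categories)) / length(a)
  q <- table(factor(b, levels = categories)) / length(b)
  sum(abs(p - q)) / 2
}

#' Per-feature fidelity report between a real and a synthetic cohort
#'
#' For every feature shared by the two cohorts, computes the W1 distance
#' (numerical, raw denormalized scale) or total-variation distance
#' (categorical) between the non-missing values, and averages them.
#'
#' @param real,synth Cohort tibbles over the same schema.
#' @param schema A `twin_schema`.
#' @return A `fidelity_report`: list with `per_feature` tibble, the
#'   `mean_distance`, and the sample sizes.
#' @export
#' @examples
#' gen <- generate_cohort(default_params(), 100, seed = 1)
#' fidelity_report(gen$cohort, gen$cohort, default_schema())$mean_distance
fidelity_report <- function(real, synth, schema) {
  feats <- intersect(intersect(cohort_feature_names(real),
                               cohort_feature_names(synth)), schema$name)
  per <- purrr::map(feats, function(f) {
    row <- schema_row(schema, f)
    d <- if (row$kind == "numerical") {
      wasserstein_1d(real[[f]], synth[[f]])
    } else {
      categorical_distance(real[[f]], synth[[f]], row$categories[[1]])
    }
    tibble::tibble(feature = f, kind = row$kind, distance = d)
  })
  per <- dplyr::bind_rows(per)
  structure(list(per_feature = per, mean_distance = mean(per$distance),
                 n_real = nrow(real), n_synth = nrow(synth)),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("Fidelity report: %d features, n_real = %d, n_synth = %d\n",
              nrow(x$per_feature), x$n_real, x$n_synth))
  cat(sprintf("Mean per-feature distance: %.4f\n", x$mean_distance))
  invisible(x)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the declared classes; a class
#' absent from both truth and prediction contributes 0, which keeps the
#' score honest on highly imbalanced targets. Invariant to class label
#' renaming; bounded in `[0, 1]`.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Declared class set (default: union of observed).
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' macro_f1(c("a", "a", "b", "b"), c("a", "b", "b", "b"))  # 11/15
macro_f1 <- function(y_true, y_pred, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  f1 <- purrr::map_dbl(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  mean(f1)
}

#' Mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors (denormalized scale).
#' @return The mean squared difference.
#' @export
mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean((y_true - y_pred)^2)
}

#' Benchmark the chain and baselines on a test cohort
#'
#' One row per chain target: macro-F1 for classification targets, MSE
#' (denormalized scale) for regression targets, for each supplied model.
#' Predictions condition on the true parent values of the test rows; rows
#' with a missing test label are scored on the observed subset.
#'
#' @param models Named list of models; the name `"xgboost"` (a
#'   `twin_chain`) plus any of `"median_mean"`, `"random"`, `"mlp"`
#'   (`twin_baseline`s).
#' @param test Test cohort tibble.
#' @param schema A `twin_schema`.
#' @param seed Seed for the random baseline's draws.
#' @return A `benchmark_table` tibble: `feature`, `metric`, one column per
#'   model.
#' @export
benchmark <- function(models, test, schema, seed = 1) {
  if (nrow(test) == 0) stop_hnc("benchmark: empty test set")
  chain <- models$xgboost
  spec <- chain$spec
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    tg <- spec$target[i]
    row <- schema_row(schema, tg)
    obs <- !is.na(test[[tg]])
    if (!any(obs)) next
    sub <- test[obs, ]
    truth <- sub[[tg]]
    metric <- if (row$kind == "numerical") "MSE" else "macro-F1"
    score <- function(pred) {
      if (metric == "MSE") mse(truth, pred) else
        macro_f1(truth, pred, row$categories[[1]])
    }
    vals <- purrr::imap_dbl(models, function(m, nm) {
      pred <- if (nm == "xgboost") {
        predict_node(chain, tg, sub)
      } else {
        predict_baseline(m, tg, sub, schema, seed = seed + i)
      }
      score(pred)
    })
    rows[[tg]] <- dplyr::bind_cols(
      tibble::tibble(feature = tg, metric = metric, n_test = sum(obs)),
      tibble::as_tibble(as.list(vals)))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_table", class(out))
  out
}
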