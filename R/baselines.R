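# Reference predictors the boosted chain is benchmarked against:
# a constant median/mean rule, a label-frequency random predictor, and a
# grid-searched multilayer perceptron trained on imputed, z-scored data.

#' Median/mean constant baseline
#'
#' For categorical targets, predicts the training median of the
#' integer-coded labels (codes in schema category order, lower median for
#' even counts — a deterministic but arbitrary choice for nominal
#' features; `mode_categorical = TRUE` switches to the most frequent
#' category). For numerical targets, predicts the training mean. The
#' prediction is constant across test rows.
#'
#' @param train Training cohort tibble.
#' @param schema A `twin_schema`.
#' @param targets Target feature names (default: the chain targets).
#' @param mode_categorical Use the modal category instead of the coded
#'   median.
#' @return A `twin_baseline` of family `"median_mean"`.
#' @export
baseline_median_mean <- function(train, schema,
                                 targets = default_chain(schema)$target,
                                 mode_categorical = FALSE) {
  preds <- purrr::map(targets, function(f) {
    row <- schema_row(schema, f)
    x <- train[[f]][!is.na(train[[f]])]
    if (row$kind == "numerical") return(mean(x))
    cats <- row$categories[[1]]
    if (mode_categorical) {
      tab <- table(factor(x, levels = cats))
      return(cats[which.max(tab)])
    }
    codes <- sort(match(x, cats))
    cats[codes[ceiling(length(codes) / 2)]]  # lower median
  })
  structure(list(family = "median_mean",
                 predictions = stats::setNames(preds, targets)),
            class = "twin_baseline")
}

#' Random baseline proportional to training label frequencies
#'
#' Categorical predictions are drawn with probabilities proportional to
#' the training label distribution; numerical predictions are drawn from
#' the training empirical distribution.
#'
#' @inheritParams baseline_median_mean
#' @return A `twin_baseline` of family `"random"`.
#' @export
baseline_random <- function(train, schema,
                            targets = default_chain(schema)$target) {
  pools <- purrr::map(targets, function(f) train[[f]][!is.na(train[[f]])])
  structure(list(family = "random", pools = stats::setNames(pools, targets)),
            class = "twin_baseline")
}

#' Multilayer-perceptron baseline
#'
#' One grid-searched MLP per target (rectified-linear hidden layers;
#' Adam or SGD; 3-fold cross-validation scored by macro-F1 / negative
#' MSE), trained on mean/most-frequent-imputed, z-scored inputs —
#' the learning baseline of the benchmark protocol.
#'
#' @inheritParams baseline_median_mean
#' @param spec A `twin_chainspec` giving each target's parents.
#' @param grid MLP grid tibble from [grid_config()].
#' @param folds CV fold count.
#' @param seed Integer seed.
#' @return A `twin_baseline` of family `"mlp"`.
#' @export
baseline_mlp <- function(train, schema, spec = default_chain(schema),
                         grid = grid_config("fast")$mlp, folds = 3L, seed = 1) {
  normalizer <- fit_normalizer(train, schema)
  imputed <- impute_cohort(train, schema, family = "vae_mlp")
  nodes <- list()
  for (i in seq_len(nrow(spec))) {
    tg <- spec$target[i]
    row <- schema_row(schema, tg)
    keep <- !is.na(train[[tg]])
    sub <- imputed[keep, ]
    X <- encode_design(sub, schema, spec$parents[[i]], normalizer)
    task <- if (row$kind == "numerical") "regression" else "classification"
    if (task == "regression") {
      y <- normalize_vec(train[[tg]][keep], normalizer, tg)
    } else {
      y <- train[[tg]][keep]
      if (length(unique(y)) < 2) {
        nodes[[tg]] <- list(constant = unique(y), categories = row$categories[[1]])
        next
      }
    }
    fit_one <- function(par, Xf, yf, seed_f) {
      mlp_fit(Xf, yf, task = task, classes = row$categories[[1]],
              hidden = par$hidden[[1]], solver = par$solver,
              lr = par$learning_rate_init, epochs = par$max_iter,
              seed = seed_f)
    }
    best <- grid[1, ]
    if (nrow(grid) > 1) {
      scores <- with_seed(seed + i, {
        fold_id <- fold_assignment(if (task == "regression") seq_along(y) else y,
                                   folds, stratify = task != "regression")
        purrr::map_dbl(seq_len(nrow(grid)), function(gi) {
          mean(purrr::map_dbl(seq_len(folds), function(k) {
            tr <- fold_id != k
            m <- fit_one(grid[gi, ], X[tr, , drop = FALSE], y[tr], seed + gi)
            if (task == "regression") {
              -mean((mlp_predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
            } else {
              macro_f1(y[!tr], mlp_predict(m, X[!tr, , drop = FALSE], "class"),
                       row$categories[[1]])
            }
          }))
        })
      })
      best <- grid[which.max(scores), ]
    }
    nodes[[tg]] <- list(model = fit_one(best, X, y, seed + i),
                        parents = spec$parents[[i]], task = task,
                        categories = row$categories[[1]], best_params = best)
  }
  structure(list(family = "mlp", nodes = nodes, normalizer = normalizer,
                 schema = schema, train_ref = train),
            class = "twin_baseline")
}

# Unified per-target prediction for any baseline family. Random draws are
# seeded by the caller.
predict_baseline <- function(baseline, target, newdata, schema, seed = NULL) {
  n <- nrow(newdata)
  switch(baseline$family,
    median_mean = rep(baseline$predictions[[target]], n),
    random = with_seed(seed, {
      pool <- baseline$pools[[target]]
      pool[sample.int(length(pool), n, replace = TRUE)]
    }),
    mlp = {
      node <- baseline$nodes[[target]]
      if (!is.null(node$constant)) return(rep(node$constant, n))
      imputed <- impute_cohort(newdata, schema, family = "vae_mlp",
                               train = baseline$train_ref)
      X <- encode_design(imputed, schema, node$parents, baseline$normalizer)
      if (node$task == "regression") {
        denormalize_vec(mlp_predict(node$model, X), baseline$normalizer, target)
      } else {
        mlp_predict(node$model, X, type = "class")
      }
    },
    stop_hnc("unknown baseline family '%s'", baseline$family))
}
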