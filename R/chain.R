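# Sequential development predictor: one gradient-boosted ensemble per
# downstream feature, conditioned on all features earlier in the chain
# (all-ancestors convention). Classification nodes use balanced class
# weights and macro-F1 model selection; regression nodes are fitted on the
# z-scored target and denormalized at prediction time. Missing parents are
# consumed natively by the boosted trees.

#' Build the numeric design matrix for a feature subset
#'
#' Numerical features are z-scored with the supplied normalizer;
#' categorical features are one-hot encoded. A missing categorical value
#' yields NA across its indicator block, so boosted trees can route it by
#' their default-direction mechanism.
#'
#' @param cohort Cohort tibble.
#' @param schema A `twin_schema`.
#' @param features Character vector of feature names (column order).
#' @param normalizer Optional `twin_normalizer`.
#' @return A numeric matrix with stable column names.
#' @keywords internal
encode_design <- function(cohort, schema, features, normalizer = NULL) {
  blocks <- purrr::map(features, function(f) {
    row <- schema_row(schema, f)
    if (row$kind == "numerical") {
      x <- cohort[[f]]
      if (!is.null(normalizer)) x <- normalize_vec(x, normalizer, f)
      m <- matrix(x, ncol = 1)
      colnames(m) <- f
      m
    } else {
      lv <- row$categories[[1]]
      m <- onehot_matrix(cohort[[f]], lv)
      m[is.na(cohort[[f]]), ] <- NA_real_
      colnames(m) <- paste0(f, "=", lv)
      m
    }
  })
  do.call(cbind, blocks)
}

#' Default predictor-chain specification
#'
#' One node per non-PTF schema feature in chronological order —
#' definitive surgery, post-surgical pathology, induction, radiotherapy
#' class, radiotherapy parameters, the four symptom scores at each of the
#' four assessments, and finally three-year relapse — each conditioned on
#' every earlier feature.
#'
#' @param schema A `twin_schema`.
#' @return A `twin_chainspec` tibble with columns `target`, `task`,
#'   `parents` (list column).
#' @export
#' @examples
#' spec <- default_chain(default_schema())
#' spec$target
default_chain <- function(schema) {
  ptf <- schema_features(schema, groups = "PTF")
  targets <- setdiff(schema$name, ptf)
  rows <- purrr::map(seq_along(targets), function(i) {
    row <- schema_row(schema, targets[i])
    task <- if (row$kind == "numerical") {
      "regression"
    } else if (length(row$categories[[1]]) == 2) "binary" else "multiclass"
    tibble::tibble(target = targets[i], task = task,
                   parents = list(c(ptf, targets[seq_len(i - 1L)])))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("twin_chainspec", class(out))
  out
}

#' Hyperparameter grids for the boosted and MLP model families
#'
#' The `"paper"` preset spans the full published search ranges
#' (3-fold cross-validation, macro-F1 / negative MSE scoring); the
#' `"fast"` preset keeps one value per hyperparameter for desk-scale runs.
#'
#' @param preset `"fast"` or `"paper"`.
#' @return A list with tibbles `boosted` and `mlp` and the fold count.
#' @export
grid_config <- function(preset = c("fast", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    boosted <- tidyr::expand_grid(
      learning_rate = c(0.01, 0.1, 0.3), max_depth = c(4L, 6L, 8L),
      min_child_weight = c(1, 3, 5), n_estimators = c(100L, 200L, 300L),
      colsample_bytree = c(0.3, 0.5))
    mlp <- tidyr::expand_grid(
      hidden = list(c(50, 50), c(100, 100), c(100, 50)),
      solver = c("adam", "sgd"), learning_rate_init = c(0.001, 0.01),
      max_iter = c(200L, 400L))
  } else {
    # classification keeps one value per hyperparameter; regression adds a
    # second, conservative learning rate so per-node CV can fall back to it
    # on targets with little signal (small-sample overfitting guard)
    boosted <- tibble::tibble(learning_rate = 0.1, max_depth = 4L,
                              min_child_weight = 5, n_estimators = 100L,
                              colsample_bytree = 0.3)
    boosted_regression <- tidyr::expand_grid(
      learning_rate = c(0.01, 0.1), max_depth = 4L, min_child_weight = 5,
      n_estimators = 100L, colsample_bytree = 0.3)
    mlp <- tibble::tibble(hidden = list(c(50, 50)), solver = "adam",
                          learning_rate_init = 0.001, max_iter = 200L)
  }
  if (preset == "paper") boosted_regression <- boosted
  list(boosted = boosted, boosted_regression = boosted_regression,
       mlp = mlp, folds = 3L)
}

# Balanced class weights: weight of class c is n / (k * n_c) over the k
# observed classes, so each class's total weight is equal.
balanced_weights <- function(y) {
  tab <- table(y)
  k <- length(tab)
  w <- as.numeric(length(y) / (k * tab[y]))
  w
}

fit_xgb_raw <- function(X, y_num, task, weights, par, nclass = NULL) {
  obj <- switch(task, binary = "binary:logistic", multiclass = "multi:softprob",
                regression = "reg:squarederror")
  params <- list(objective = obj, eta = par$learning_rate,
                 max_depth = par$max_depth, min_child_weight = par$min_child_weight,
                 colsample_bytree = par$colsample_bytree, nthread = 1, seed = 0)
  if (task == "multiclass") params$num_class <- nclass
  if (task != "regression") {
    params$eval_metric <- if (task == "binary") "logloss" else "mlogloss"
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y_num, weight = weights)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = par$n_estimators,
                     verbose = 0)
}

predict_xgb_raw <- function(model, X, task, nclass = NULL) {
  pr <- stats::predict(model, xgboost::xgb.DMatrix(X))
  if (task == "multiclass" && is.null(dim(pr))) {
    pr <- matrix(pr, ncol = nclass, byrow = TRUE)
  }
  if (task == "binary") pr <- cbind(1 - pr, pr)
  pr
}

# Stratified k-fold assignment (classification) or plain k-fold.
fold_assignment <- function(y, k, stratify) {
  n <- length(y)
  folds <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Fit one predictor node with grid search
#'
#' Fits the boosted ensemble for `target` given its parents: rows with a
#' missing target are dropped for this node only; classification uses
#' balanced class weights; a grid with more than one point is searched by
#' stratified 3-fold cross-validation scored with macro-F1 (classification)
#' or negative MSE (regression), ties broken toward fewer trees then
#' shallower depth. A target with a single observed class degenerates to a
#' constant predictor with a warning.
#'
#' @param train Training cohort tibble.
#' @param schema A `twin_schema`.
#' @param target Target feature name.
#' @param parents Character vector of parent feature names.
#' @param grid Boosted-grid tibble (see [grid_config()]).
#' @param normalizer A `twin_normalizer` fitted on `train`.
#' @param folds Number of CV folds.
#' @param seed Integer seed for fold assignment.
#' @return A fitted node (list) used by [fit_chain()].
#' @export
fit_node <- function(train, schema, target, parents, grid,
                     normalizer = fit_normalizer(train, schema), folds = 3L,
                     seed = 1) {
  row <- schema_row(schema, target)
  task <- if (row$kind == "numerical") "regression"
          else if (length(row$categories[[1]]) == 2) "binary" else "multiclass"
  keep <- !is.na(train[[target]])
  sub <- train[keep, ]
  X <- encode_design(sub, schema, parents, normalizer)

  node <- list(target = target, parents = parents, task = task,
               categories = row$categories[[1]],
               lo = row$lo, hi = row$hi, integer_valued = row$integer_valued,
               n_train = nrow(sub))

  if (task == "regression") {
    y <- normalize_vec(sub[[target]], normalizer, target)
    weights <- rep(1, nrow(sub))
    y_num <- y
  } else {
    y <- sub[[target]]
    obs_classes <- sort(unique(y))
    if (length(obs_classes) < 2) {
      warn_hnc("target '%s' has %d observed class(es); constant predictor",
               target, length(obs_classes))
      node$constant <- if (length(obs_classes)) obs_classes else node$categories[1]
      node$cv_score <- NA_real_
      return(node)
    }
    weights <- balanced_weights(y)
    y_num <- as.numeric(factor(y, levels = node$categories)) - 1
    if (task == "binary") y_num <- as.numeric(y_num > 0)
  }
  nclass <- if (task == "multiclass") length(node$categories) else NULL

  best <- grid[1, ]
  best_score <- NA_real_
  if (nrow(grid) > 1) {
    scores <- with_seed(seed, {
      fold_id <- fold_assignment(if (task == "regression") seq_along(y_num) else y,
                                 folds, stratify = task != "regression")
      purrr::map_dbl(seq_len(nrow(grid)), function(gi) {
        par <- grid[gi, ]
        mean(purrr::map_dbl(seq_len(folds), function(k) {
          tr <- fold_id != k
          m <- fit_xgb_raw(X[tr, , drop = FALSE], y_num[tr], task, weights[tr],
                           par, nclass)
          pr <- predict_xgb_raw(m, X[!tr, , drop = FALSE], task, nclass)
          if (task == "regression") {
            -mean((pr - y_num[!tr])^2)
          } else {
            pred <- node$categories[max.col(pr, ties.method = "first")]
            macro_f1(y[!tr], pred, node$categories)
          }
        }))
      })
    })
    # ties toward fewer trees, then shallower depth
    ord <- order(-scores, grid$n_estimators, grid$max_depth)
    best <- grid[ord[1], ]
    best_score <- scores[ord[1]]
  }

  node$model <- fit_xgb_raw(X, y_num, task, weights, best, nclass)
  node$best_params <- best
  node$cv_score <- best_score
  if (task == "regression") {
    fit_norm <- predict_xgb_raw(node$model, X, task)
    resid <- denormalize_vec(y_num, normalizer, target) -
      denormalize_vec(fit_norm, normalizer, target)
    node$resid_sd <- sqrt(mean(resid^2))
  }
  node
}

#' Fit the full predictor chain
#'
#' Fits every node of the chain specification in order on the training
#' cohort. Deterministic given `seed`.
#'
#' @param train Training cohort tibble.
#' @param schema A `twin_schema`.
#' @param spec A `twin_chainspec` (default [default_chain()]).
#' @param grid A [grid_config()] list.
#' @param seed Integer seed.
#' @return A `twin_chain` with the fitted nodes and the train-fitted
#'   normalizer.
#' @export
#' @examples
#' gen <- generate_cohort(default_params(), 120, seed = 1)
#' chain <- fit_chain(gen$cohort, default_schema(), seed = 1)
fit_chain <- function(train, schema, spec = default_chain(schema),
                      grid = grid_config("fast"), seed = 1) {
  normalizer <- fit_normalizer(train, schema)
  nodes <- list()
  for (i in seq_len(nrow(spec))) {
    g <- if (spec$task[i] == "regression") {
      grid$boosted_regression %||% grid$boosted
    } else grid$boosted
    nodes[[spec$target[i]]] <- fit_node(
      train, schema, spec$target[i], spec$parents[[i]], g,
      normalizer = normalizer, folds = grid$folds, seed = seed + i)
  }
  structure(list(schema = schema, spec = spec, normalizer = normalizer,
                 nodes = nodes), class = "twin_chain")
}

#' Predict one chain node on new data
#'
#' @param chain A `twin_chain`.
#' @param target Node name.
#' @param newdata Cohort tibble containing the node's parents.
#' @param type `"response"` (class label / denormalized numeric) or
#'   `"prob"` (class-probability matrix).
#' @return Predictions on the denormalized scale.
#' @export
predict_node <- function(chain, target, newdata, type = c("response", "prob")) {
  type <- match.arg(type)
  node <- chain$nodes[[target]]
  if (is.null(node)) stop_hnc("no fitted node for '%s'", target)
  n <- nrow(newdata)
  if (!is.null(node$constant)) {
    if (type == "prob") {
      pr <- matrix(0, n, length(node$categories),
                   dimnames = list(NULL, node$categories))
      pr[, node$constant] <- 1
      return(pr)
    }
    return(rep(node$constant, n))
  }
  X <- encode_design(newdata, chain$schema, node$parents, chain$normalizer)
  nclass <- if (node$task == "multiclass") length(node$categories) else NULL
  pr <- predict_xgb_raw(node$model, X, node$task, nclass)
  if (node$task == "regression") {
    return(denormalize_vec(as.numeric(pr), chain$normalizer, target))
  }
  colnames(pr) <- node$categories
  if (type == "prob") pr else node$categories[max.col(pr, ties.method = "first")]
}

# Fill the given targets of a partially observed record table, in chain
# order, feeding predictions forward. Structural rules are respected:
# gated features stay NA when their gate fails. Returns the record with a
# "relapse_prob" attribute once the relapse node has been filled.
chain_fill <- function(chain, record, targets, mode = c("expected", "sampled")) {
  mode <- match.arg(mode)
  schema <- chain$schema
  relapse_prob <- attr(record, "relapse_prob")
  for (tg in intersect(chain$spec$target, targets)) {
    node <- chain$nodes[[tg]]
    open <- purrr::map_lgl(seq_len(nrow(record)),
                           ~ structurally_observed(schema, tg, record[.x, ]))
    vals <- if (node$task == "regression") rep(NA_real_, nrow(record)) else
      rep(NA_character_, nrow(record))
    if (any(open)) {
      sub <- record[open, ]
      if (node$task == "regression") {
        pred <- predict_node(chain, tg, sub)
        if (mode == "sampled") {
          pred <- pred + stats::rnorm(length(pred), 0, node$resid_sd %||% 0)
          if (node$integer_valued) pred <- round(pred)
        }
        if (!is.na(node$lo)) pred <- clip(pred, node$lo, node$hi)
        vals[open] <- pred
      } else {
        pr <- predict_node(chain, tg, sub, type = "prob")
        idx <- if (mode == "expected") {
          max.col(pr, ties.method = "first")
        } else {
          sample_rows(pr)
        }
        vals[open] <- node$categories[idx]
        if (tg == "relapse_yr3") {
          relapse_prob <- rep(NA_real_, nrow(record))
          relapse_prob[open] <- pr[, "True"]
        }
      }
    }
    record[[tg]] <- vals
  }
  attr(record, "relapse_prob") <- relapse_prob
  record
}

#' Simulate a patient's full record under a treatment plan
#'
#' Starting from a complete pre-treatment profile and the three first-cycle
#' actions, fills every downstream feature in chain order, feeding
#' predictions forward. `"expected"` mode takes the modal class /
#' regression mean and is deterministic; `"sampled"` mode draws classes
#' from predicted probabilities and adds Gaussian noise with each node's
#' training residual sd to regression predictions (clipped to bounds,
#' rounded for integer-valued scores).
#'
#' @param chain A `twin_chain`.
#' @param ptf_row One-row cohort tibble with complete PTF columns.
#' @param actions Named list/vector with `definitive`, `induction`,
#'   `radio_chemo` (legal labels).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Integer seed (sampled mode).
#' @return A one-row tibble with the full record; attribute
#'   `"relapse_prob"` carries the predicted relapse probability.
#' @export
rollout <- function(chain, ptf_row, actions, mode = c("expected", "sampled"),
                    seed = NULL) {
  mode <- match.arg(mode)
  out <- rollout_cohort(chain, ptf_row, actions, mode = mode, seed = seed)
  out
}

# Vectorized rollout: one shared action plan applied to every row of a
# PTF cohort.
rollout_cohort <- function(chain, ptf_cohort, actions, mode = c("expected", "sampled"),
                          seed = NULL) {
  mode <- match.arg(mode)
  actions <- as.list(actions)
  names(actions) <- sub("^radio_chemo$", "radio/chemo", names(actions))
  for (a in names(ACTION_LABELS)) {
    if (is.null(actions[[a]])) stop_hnc("missing action '%s'", a)
    if (!actions[[a]] %in% ACTION_LABELS[[a]]) {
      stop_hnc("unknown label '%s' for action '%s'", actions[[a]], a)
    }
  }
  record <- ptf_cohort
  record$definitive <- actions$definitive
  record$induction <- actions$induction
  record$`radio/chemo` <- actions$`radio/chemo`
  targets <- setdiff(chain$spec$target, names(ACTION_LABELS))
  with_seed(seed, chain_fill(chain, record, targets, mode))
}
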