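# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the VAE training history
#'
#' @param x A `twin_vae`.
#' @param ... Unused.
#' @return The per-epoch loss-component tibble.
#' @export
tidy.twin_vae <- function(x, ...) x$history

#' @rdname tidy.twin_vae
#' @export
glance.twin_vae <- function(x, ...) {
  last <- if (nrow(x$history)) utils::tail(x$history, 1) else
    tibble::tibble(recon_numerical = NA_real_, recon_categorical = NA_real_,
                   kl = NA_real_, total = NA_real_)
  tibble::tibble(
    n_train = x$n_train, input_dim = x$input_dim,
    latent_dim = x$config$latent_dim, epochs = x$config$epochs,
    final_total = last$total, final_kl = last$kl
  )
}

#' Tidy a fitted predictor chain
#'
#' One row per node with its task, training size, selected
#' hyperparameters, and cross-validated score (NA when the grid had a
#' single point).
#'
#' @param x A `twin_chain`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.twin_chain <- function(x, ...) {
  purrr::imap(x$nodes, function(node, nm) {
    tibble::tibble(
      target = nm, task = node$task, n_train = node$n_train,
      constant = !is.null(node$constant), cv_score = node$cv_score %||% NA_real_,
      resid_sd = node$resid_sd %||% NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.twin_chain
#' @export
glance.twin_chain <- function(x, ...) {
  nd <- tidy(x)
  tibble::tibble(n_nodes = nrow(nd), n_constant = sum(nd$constant),
                 n_classification = sum(nd$task != "regression"),
                 n_regression = sum(nd$task == "regression"))
}

#' Plot the per-feature fidelity distances
#'
#' @param object A `fidelity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- dplyr::arrange(object$per_feature, .data$distance)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$feature,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$mean_distance, linetype = 2) +
    ggplot2::labs(x = "distance (W1 / total variation)", y = NULL,
                  title = "Real-vs-synthetic per-feature fidelity",
                  subtitle = sprintf("mean distance %.3f", object$mean_distance)) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark table as per-target model comparison
#'
#' @param object A `benchmark_table`.
#' @param ... Unused.
#' @return A ggplot, faceted by metric.
#' @export
autoplot.benchmark_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -c("feature", "metric", "n_test"),
                              names_to = "model", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$feature,
                                     colour = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Predictive benchmark: macro-F1 (higher better) / MSE (lower better)") +
    ggplot2::theme_minimal()
}

#' Plot a paired treatment-plan comparison
#'
#' @param object A `plan_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plan_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = c("mean_relapse_prob", "mean_symptom_burden"),
                              names_to = "outcome", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$plan, y = .data$value,
                                     fill = .data$plan)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Treatment-plan comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Overlay real and synthetic feature distributions
#'
#' Violin-style comparison of each selected numerical feature between a
#' real and a synthetic cohort.
#'
#' @param real,synth Cohort tibbles.
#' @param schema A `twin_schema`.
#' @param features Numerical features to plot (default: all shared).
#' @return A ggplot.
#' @export
plot_cohort_overlay <- function(real, synth, schema, features = NULL) {
  num <- schema_features(schema, kind = "numerical")
  features <- features %||%
    intersect(intersect(num, names(real)), names(synth))
  stack <- function(cohort, source) {
    cohort[, features] |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "feature") |>
      dplyr::mutate(source = source)
  }
  df <- dplyr::bind_rows(stack(real, "real"), stack(synth, "synthetic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$value,
                                   fill = .data$source)) +
    ggplot2::geom_violin(na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Feature-wise real vs synthetic distributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
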