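# Synthetic-cohort generator.
#
# Emulates the published marginal statistics of the reference cohort
# (categorical probabilities = printed counts / N; numerical moments as
# printed), the mined first-cycle treatment-sequence frequencies, the
# structural missingness rules (post-surgical pathology only after surgery,
# radiotherapy parameters only under radiotherapy, partially labelled
# three-year relapse), and planted dependencies — treatment intensity
# shifting symptom burden and relapse log-odds, staging shifting treatment
# propensity and pathology — so downstream predictors have learnable
# signal. All planted effects are centred so the marginal means remain at
# their printed values.

#' Default generator parameters from the published tables
#'
#' Category probabilities are printed counts normalised within each
#' variable (for `ENE` and `Margin`, conditional on definitive surgery;
#' for `rt_type`, conditional on radiotherapy); numerical marginals carry
#' the printed (mean, sd); treatment-sequence probabilities are the eight
#' mined pattern counts over their total (651). Planted effect sizes are
#' package defaults documented in the methods vignette — parameters, not
#' published quantities; [zero_effects()] switches them all off.
#'
#' @param schema A `twin_schema`; defaults to [default_schema()].
#' @return A `twin_params` list with elements `schema`, `marginals`,
#'   `sequence`, `effects`, `missingness`.
#' @export
#' @examples
#' p <- default_params()
#' p$marginals$age
#' sum(p$sequence$prob)
default_params <- function(schema = default_schema()) {
  demo <- cohort_demographics()
  marginals <- list()
  for (i in seq_len(nrow(schema))) {
    row <- schema[i, ]
    if (row$kind == "numerical") {
      marginals[[row$name]] <- c(mean = row$mean, sd = row$sd)
    } else if (!row$name %in% names(ACTION_LABELS) && row$name != "relapse_yr3") {
      counts <- demo$count[demo$variable == row$name]
      names(counts) <- demo$category[demo$variable == row$name]
      counts <- counts[row$categories[[1]]]  # schema order; drops e.g. ENE "Unknown"
      marginals[[row$name]] <- counts / sum(counts)
    }
  }
  marginals$relapse_yr3 <- c(False = 153, True = 35) / 188

  seq_tab <- treatment_sequences()
  seq_tab$prob <- seq_tab$count / sum(seq_tab$count)
  seq_tab$intensity <- (seq_tab$definitive == "yes") + (seq_tab$induction == "yes") +
    match(seq_tab$radio_chemo, ACTION_LABELS$`radio/chemo`) - 1L

  params <- list(
    schema = schema,
    marginals = marginals,
    sequence = seq_tab[, c("pattern", "prob", "definitive", "induction",
                           "radio_chemo", "intensity")],
    effects = list(
      # symptom elevation per unit centred treatment intensity, by phase
      symptom = c(endrt = 1.2, wk6 = 0.7, m3 = 0.4, m12 = 0.2),
      # coupling of each phase's score to the centred baseline score
      baseline_coupling = c(endrt = 0.65, wk6 = 0.20, m3 = 0.15, m12 = 0.10),
      # coupling of each post-baseline phase to the previous phase's score
      # (symptom persistence; endrt has no earlier on-treatment phase)
      phase_coupling = c(endrt = 0, wk6 = 0.55, m3 = 0.55, m12 = 0.50),
      relapse_intensity = -1.5,   # aggressive treatment lowers relapse log-odds
      relapse_stage = 0.7,        # higher stage raises relapse log-odds
      relapse_p16 = -0.9,         # HPV-positive disease is protective
      propensity_surgery = 1.0,   # early T-stage tilts toward definitive surgery
      propensity_induction = 1.0, # nodal burden tilts toward induction
      propensity_rt = 0.6,        # overall stage tilts toward chemoradiotherapy
      ene_stage = 1.4,            # stage raises P(ENE positive)
      margin_stage = 1.2,         # stage tilts margins toward positive classes
      rt_type_age = 1.6,          # younger patients tilt toward IMPT
      rt_type_stage = 0.8,        # stage tilts technique choice as well
      dose_chemo = 300,           # cGy shift for concurrent-chemo patients
      fraction_chemo = 1.3        # fraction-count shift for concurrent chemo
    ),
    missingness = list(
      relapse_labeled_frac = 188 / 676,
      prs_missing_rate = 0
    )
  )
  class(params) <- c("twin_params", "list")
  params
}

#' Zero all planted effect coefficients
#'
#' Returns the parameters with every planted dependency switched off, so
#' features are drawn independently from their marginals (pure
#' marginal-recovery mode).
#'
#' @param params A `twin_params`.
#' @return The modified `twin_params`.
#' @export
zero_effects <- function(params) {
  params$effects <- purrr::map(params$effects, ~ .x * 0)
  params
}

# ---- clipped-normal moment machinery --------------------------------------

# Mean and sd of clip(Normal(mu, sigma), lo, hi) in closed form.
clipped_normal_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  mid <- Fb - Fa
  m1 <- lo * Fa + hi * (1 - Fb) + mu * mid - sigma * (fb - fa)
  # E[X^2] of the clipped variable
  mid2 <- mu^2 * mid + 2 * mu * sigma * (fa - fb) + sigma^2 * (mid + a * fa - b * fb)
  m2 <- lo^2 * Fa + hi^2 * (1 - Fb) + mid2
  v <- pmax(m2 - m1^2, 0)
  c(mean = m1, sd = sqrt(v))
}

# Invert the clipped-normal moment map: find (mu, sigma) of the underlying
# normal such that the clipped draw has the target mean and sd. Used for the
# bounded 0-10 symptom scores so their realised marginals match the printed
# moments despite clipping.
solve_clipped_params <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    m <- clipped_normal_moments(par[1], exp(par[2]), lo, hi)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Moment-matched lognormal parameters (used for nonnegative right-skewed
# tobacco covariates).
lognormal_params <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Draw n values for a numerical schema feature from its marginal.
sample_numeric_marginal <- function(row, marg, n) {
  m <- marg[["mean"]]; s <- marg[["sd"]]
  bounded <- !is.na(row$lo) && !is.na(row$hi)
  if (identical(row$dist, "lognormal")) {
    lp <- lognormal_params(m, s)
    x <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  } else if (bounded) {
    cp <- solve_clipped_params(m, s, row$lo, row$hi)
    x <- clip(stats::rnorm(n, cp$mu, cp$sigma), row$lo, row$hi)
  } else {
    x <- stats::rnorm(n, m, s)
  }
  if (row$integer_valued) x <- round(x)
  x
}

# Row-wise categorical draw from an n x k probability matrix (one uniform
# per row; deterministic under the session RNG).
sample_rows <- function(prob_matrix) {
  prob_matrix <- prob_matrix / rowSums(prob_matrix)
  cum <- t(apply(prob_matrix, 1, cumsum))
  u <- stats::runif(nrow(prob_matrix))
  rowSums(cum < u) + 1L
}

# Per-patient multinomial probabilities with an exponential tilt that is
# calibrated (via per-category log-offsets, fixed-point iteration) so the
# population-average probability of every category equals `base`. This is
# how planted covariate effects are injected without moving the marginal
# distribution away from the printed one.
calibrated_tilt <- function(base, tilt) {
  n <- nrow(tilt); k <- length(base)
  logw <- matrix(log(base), n, k, byrow = TRUE) + tilt
  delta <- numeric(k)
  for (it in 1:200) {
    P <- softmax_rows(logw + matrix(delta, n, k, byrow = TRUE))
    colm <- colMeans(P)
    if (max(abs(colm - base)) < 1e-10) break
    delta <- delta + log(base) - log(colm)
  }
  P
}

# Calibrated per-patient Bernoulli probabilities: intercept solved so the
# mean probability equals `p_target`.
calibrated_logistic <- function(p_target, lin) {
  if (all(lin == 0)) return(rep(p_target, length(lin)))
  f <- function(d) mean(logistic(lin + d)) - p_target
  d <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
  logistic(lin + d)
}

# Numeric stage scores used by the planted dependencies. tx/nx map to the
# probability-weighted mean of the defined levels.
T_STAGE_NUM <- c(t0 = 0, t1 = 1, t2 = 2, t3 = 3, t4 = 4, tx = NA)
N_STAGE_NUM <- c(n0 = 0, n1 = 1, n2 = 2, n2a = 2, n2b = 2, n2c = 2.5, n3 = 3, nx = NA)

# Standardized T-stage, N-stage, and combined stage scores; moments are
# the analytic population moments under the marginal probabilities, so the
# scores are deterministic transforms of the sampled labels.
stage_scores <- function(t_nominal, n_nominal, marginals) {
  zscore <- function(map, probs, labels) {
    p <- probs[names(map)]
    fill <- sum(map[!is.na(map)] * p[!is.na(map)]) / sum(p[!is.na(map)])
    map[is.na(map)] <- fill
    mu <- sum(map * p)
    v <- sum(map^2 * p) - mu^2
    unname((map[labels] - mu) / sqrt(v))
  }
  t_z <- zscore(T_STAGE_NUM, marginals$t_nominal, t_nominal)
  n_z <- zscore(N_STAGE_NUM, marginals$n_nominal, n_nominal)
  list(t_z = t_z, n_z = n_z, combined = (t_z + n_z) / sqrt(2))
}

#' Sample first-cycle treatment sequences
#'
#' Draws treatment-sequence patterns from the mined pattern distribution
#' and decodes them into the three first-cycle action variables.
#'
#' @param params A `twin_params`.
#' @param n Number of sequences to draw.
#' @param seed Optional integer seed.
#' @return A tibble with columns `pattern`, `definitive`, `induction`,
#'   `radio_chemo`.
#' @export
#' @examples
#' sample_treatment_sequence(default_params(), n = 5, seed = 1)
sample_treatment_sequence <- function(params, n = 1, seed = NULL) {
  with_seed(seed, {
    idx <- sample.int(nrow(params$sequence), n, replace = TRUE,
                      prob = params$sequence$prob)
    tibble::tibble(
      pattern = params$sequence$pattern[idx],
      definitive = params$sequence$definitive[idx],
      induction = params$sequence$induction[idx],
      radio_chemo = params$sequence$radio_chemo[idx]
    )
  })
}

#' Generate a synthetic patient cohort with planted ground truth
#'
#' Samples `n` patients: pre-treatment features from the published
#' marginals, first-cycle actions from the mined sequence distribution
#' (tilted by staging when the propensity effect is on), post-intervention
#' outcomes conditional on the actions with structural masking, bounded
#' 0-10 symptom trajectories whose conditional means shift with centred
#' treatment intensity and baseline symptom burden, and a partially
#' labelled Bernoulli three-year relapse outcome on the logistic scale.
#'
#' @param params A `twin_params` (see [default_params()]).
#' @param n Number of patients (`n >= 0`).
#' @param seed Integer seed; identical `(params, n, seed)` give identical
#'   output.
#' @return A list with `cohort` (tibble passing [validate_cohort()]) and
#'   `truth` (per-patient latent intensity, stage score, assigned pattern,
#'   and true relapse probability).
#' @export
#' @examples
#' gen <- generate_cohort(default_params(), n = 50, seed = 42)
#' dplyr::glimpse(gen$cohort[, 1:6])
generate_cohort <- function(params, n, seed = NULL) {
  if (n < 0) stop_hnc("n must be >= 0")
  schema <- params$schema
  eff <- params$effects
  if (n == 0) {
    cols <- c(list(patient_id = character(0)),
              stats::setNames(purrr::map(seq_len(nrow(schema)), function(i) {
                if (schema$kind[i] == "categorical") character(0) else numeric(0)
              }), schema$name))
    truth <- tibble::tibble(patient_id = character(0), pattern_index = integer(0),
                            pattern = character(0), intensity = numeric(0),
                            intensity_centered = numeric(0), stage_score = numeric(0),
                            relapse_prob = numeric(0), relapse_labeled = logical(0))
    return(list(cohort = tibble::as_tibble(cols), truth = truth))
  }

  with_seed(seed, {
    ids <- patient_ids(n)
    values <- list()

    # ---- PTF ---------------------------------------------------------------
    ptf_names <- schema_features(schema, groups = "PTF")
    for (f in ptf_names) {
      row <- schema_row(schema, f)
      if (row$kind == "categorical") {
        p <- params$marginals[[f]]
        values[[f]] <- sample(names(p), n, replace = TRUE, prob = p)
      } else {
        values[[f]] <- sample_numeric_marginal(row, params$marginals[[f]], n)
      }
    }

    sz <- stage_scores(values$t_nominal, values$n_nominal, params$marginals)
    s <- sz$combined
    age_row <- schema_row(schema, "age")
    age_z <- (values$age - age_row$mean) / age_row$sd

    # ---- ACTIONS: pattern assignment, action-specific propensities ---------
    # Early T-stage favours definitive surgery, nodal burden favours
    # induction, overall stage favours concurrent chemoradiotherapy; the
    # tilt is calibrated so the pattern marginals stay at the mined
    # frequencies.
    seq_tab <- params$sequence
    ibar <- sum(seq_tab$prob * seq_tab$intensity)
    cI <- seq_tab$intensity - ibar
    ds_k <- as.numeric(seq_tab$definitive == "yes")
    ic_k <- as.numeric(seq_tab$induction == "yes")
    rt_k <- match(seq_tab$radio_chemo, ACTION_LABELS$`radio/chemo`) - 1L
    rt_bar <- sum(seq_tab$prob * rt_k)
    tilt <- outer(-eff$propensity_surgery * sz$t_z, ds_k) +
      outer(eff$propensity_induction * sz$n_z, ic_k) +
      outer(eff$propensity_rt * s, rt_k - rt_bar)
    pat_idx <- sample_rows(calibrated_tilt(seq_tab$prob, tilt))
    values$definitive <- seq_tab$definitive[pat_idx]
    values$induction <- seq_tab$induction[pat_idx]
    values$`radio/chemo` <- seq_tab$radio_chemo[pat_idx]
    intensity <- seq_tab$intensity[pat_idx]
    ci <- intensity - ibar
    var_intensity <- sum(seq_tab$prob * cI^2)

    # ---- PIO ---------------------------------------------------------------
    # Calibration is done within the structurally observed subset, so the
    # conditional marginals (given surgery / radiotherapy) match the
    # printed tables.
    surgical <- values$definitive == "yes"
    ene <- rep(NA_character_, n)
    u_ene <- stats::runif(n)
    if (any(surgical)) {
      prob_pos <- calibrated_logistic(params$marginals$ENE[["Positive"]],
                                      eff$ene_stage * s[surgical])
      ene[surgical] <- ifelse(u_ene[surgical] < prob_pos, "Positive", "Negative")
    }
    values$ENE <- ene

    marg_m <- params$marginals$Margin
    m_dir <- c("Negative" = -1, "Positive" = 1.2, "<1mm" = 0.6, "<2mm" = 0.4,
               "<1m" = 0.2, "<2m" = 0.3, "1mm" = 0.5)[names(marg_m)]
    margin <- rep(NA_character_, n)
    u_m <- stats::runif(n)
    if (any(surgical)) {
      Pm <- calibrated_tilt(marg_m, outer(eff$margin_stage * s[surgical], m_dir))
      cum <- t(apply(Pm, 1, cumsum))
      margin[surgical] <- names(marg_m)[rowSums(cum < u_m[surgical]) + 1L]
    }
    values$Margin <- margin

    rt <- values$`radio/chemo` != "no"
    chemo <- values$`radio/chemo` == "yes_with_concurrent_chemotherapy"
    marg_rt <- params$marginals$rt_type
    rt_dir <- c("IMPT" = -1, "Vmat" = 0, "IMRT" = 0.5, "3d Conformal" = 1,
                "Other" = 0)[names(marg_rt)]
    rt_type <- rep(NA_character_, n)
    u_rt <- stats::runif(n)
    rt_dir2 <- c("IMPT" = -0.5, "Vmat" = 0, "IMRT" = 0.5, "3d Conformal" = 1,
                 "Other" = 0)[names(marg_rt)]
    if (any(rt)) {
      Prt <- calibrated_tilt(marg_rt, outer(eff$rt_type_age * age_z[rt], rt_dir) +
                               outer(eff$rt_type_stage * s[rt], rt_dir2))
      cum <- t(apply(Prt, 1, cumsum))
      rt_type[rt] <- names(marg_rt)[rowSums(cum < u_rt[rt]) + 1L]
    }
    values$rt_type <- rt_type

    # chemo-shift centred on P(concurrent chemo | radiotherapy) so the
    # conditional-on-RT mean stays at the printed value
    p_rt <- sum(seq_tab$prob[seq_tab$radio_chemo != "no"])
    p_chemo_rt <- sum(seq_tab$prob[seq_tab$radio_chemo ==
                                     "yes_with_concurrent_chemotherapy"]) / p_rt
    chemo_c <- as.numeric(chemo) - p_chemo_rt
    for (f in c("rt_dose", "rt_fraction")) {
      row <- schema_row(schema, f)
      marg <- params$marginals[[f]]
      shift <- if (f == "rt_dose") eff$dose_chemo else eff$fraction_chemo
      resid_sd <- sqrt(max(marg[["sd"]]^2 -
                             shift^2 * p_chemo_rt * (1 - p_chemo_rt), 1e-8))
      x <- marg[["mean"]] + shift * chemo_c + stats::rnorm(n, 0, resid_sd)
      if (row$integer_valued) x <- round(x)
      x[!rt] <- NA_real_
      values[[f]] <- x
    }

    # ---- PRS ---------------------------------------------------------------
    # Each phase's score couples to the centred baseline score, to the
    # previous phase (symptom persistence), and to centred treatment
    # intensity; residual noise is scaled so the marginal matches the
    # clipped-normal moment inversion of the printed (mean, sd).
    prev_phase <- c(endrt = NA, wk6 = "endrt", m3 = "wk6", m12 = "m3")
    for (ph in PRS_PHASES) {
      lam_b <- eff$baseline_coupling[[ph]]
      lam_p <- eff$phase_coupling[[ph]]
      beta <- eff$symptom[[ph]]
      for (sym in SYMPTOMS) {
        f <- paste0("mdasi_", ph, "_", sym)
        row <- schema_row(schema, f)
        marg <- params$marginals[[f]]
        b_marg <- params$marginals[[paste0("mdasi_baseline_", sym)]]
        cp <- solve_clipped_params(marg[["mean"]], marg[["sd"]], row$lo, row$hi)
        base_dev <- values[[paste0("mdasi_baseline_", sym)]] - b_marg[["mean"]]
        prev_var <- 0
        prev_dev <- 0
        if (!is.na(prev_phase[[ph]]) && lam_p != 0) {
          pf <- paste0("mdasi_", prev_phase[[ph]], "_", sym)
          p_marg <- params$marginals[[pf]]
          prev_dev <- values[[pf]] - p_marg[["mean"]]
          prev_var <- p_marg[["sd"]]^2
        }
        resid_sd <- sqrt(max(cp$sigma^2 - lam_b^2 * b_marg[["sd"]]^2 -
                               lam_p^2 * prev_var - beta^2 * var_intensity, 0.25))
        x <- cp$mu + lam_b * base_dev + lam_p * prev_dev + beta * ci +
          stats::rnorm(n, 0, resid_sd)
        x <- round(clip(x, row$lo, row$hi))
        if (params$missingness$prs_missing_rate > 0) {
          x[stats::runif(n) < params$missingness$prs_missing_rate] <- NA_real_
        }
        values[[f]] <- x
      }
    }

    # ---- TPO ---------------------------------------------------------------
    p16_yes <- as.numeric(values$p16_hpv_postive == "Yes")
    p16_c <- p16_yes - params$marginals$p16_hpv_postive[["Yes"]]
    lin <- eff$relapse_intensity * ci + eff$relapse_stage * s + eff$relapse_p16 * p16_c
    relapse_prob <- calibrated_logistic(params$marginals$relapse_yr3[["True"]], lin)
    relapse <- ifelse(stats::runif(n) < relapse_prob, "True", "False")
    labeled <- stats::runif(n) < params$missingness$relapse_labeled_frac
    relapse[!labeled] <- NA_character_
    values$relapse_yr3 <- relapse

    cohort <- as_cohort(tibble::as_tibble(values[schema$name]), patient_id = ids)
    truth <- tibble::tibble(
      patient_id = ids, pattern_index = pat_idx,
      pattern = seq_tab$pattern[pat_idx], intensity = intensity,
      intensity_centered = ci, stage_score = s,
      relapse_prob = relapse_prob, relapse_labeled = labeled
    )
    list(cohort = cohort, truth = truth)
  })
}
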