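# Three-step sequential decision environment wrapping the VAE patient
# generator and the predictor chain. Episodes follow the first-cycle
# action structure: step 0 chooses definitive surgery (binary), step 1
# induction therapy (binary), step 2 the radiotherapy class (ternary).
# Intermediate steps fill the stage-appropriate predicted outcomes so that
# later decisions can be state-dependent; the final step completes the
# rollout and returns the scalar reward
#   -relapse_weight * P(relapse_yr3)
#   -symptom_weight * mean(end-of-RT symptom burden) / 10.
# The reward shape is a package choice (configurable), not a published
# quantity.

STEP_ACTIONS <- list(
  definitive = c("no", "yes"),
  induction = c("no", "yes"),
  `radio/chemo` = c("no", "yes", "yes_with_concurrent_chemotherapy")
)

#' Reward configuration for the decision environment
#'
#' @param relapse_weight Weight on the predicted relapse probability.
#' @param symptom_weight Weight on the mean predicted end-of-radiotherapy
#'   symptom burden, normalized to `[0, 1]` by the 0-10 scale maximum.
#' @param symptoms Symptom set entering the burden (default the four
#'   modelled symptoms).
#' @return A `reward_config` list.
#' @export
reward_config <- function(relapse_weight = 1, symptom_weight = 0.5,
                          symptoms = SYMPTOMS) {
  stopifnot(is.finite(relapse_weight), is.finite(symptom_weight))
  structure(list(relapse_weight = relapse_weight,
                 symptom_weight = symptom_weight, symptoms = symptoms),
            class = "reward_config")
}

#' Create the three-step treatment decision environment
#'
#' @param vae A trained `twin_vae` (patient generator).
#' @param chain A fitted `twin_chain` (development predictor).
#' @param reward A [reward_config()].
#' @param mode `"expected"` (deterministic predictions) or `"sampled"`.
#' @return A `twin_env` with mutable episode state; drive it with
#'   [env_reset()] and [env_step()].
#' @export
#' @examples
#' \donttest{
#' gen <- generate_cohort(default_params(), 150, seed = 1)
#' vae <- train_vae(gen$cohort, default_schema(), vae_config(epochs = 30))
#' chain <- fit_chain(gen$cohort, default_schema(), seed = 1)
#' env <- twin_env(vae, chain)
#' obs <- env_reset(env, seed = 3)
#' step <- env_step(env, 0); step <- env_step(env, 0); step <- env_step(env, 1)
#' step$reward
#' }
twin_env <- function(vae, chain, reward = reward_config(),
                     mode = c("expected", "sampled")) {
  mode <- match.arg(mode)
  state <- new.env(parent = emptyenv())
  state$step_index <- NA_integer_
  state$record <- NULL
  state$done <- TRUE
  structure(list(vae = vae, chain = chain, reward = reward, mode = mode,
                 state = state),
            class = "twin_env")
}

# Flatten the PTF block of a record into the published observation
# encoding: numerical features z-scored, categorical features one-hot,
# ordering fixed by the schema.
env_observation <- function(env, record) {
  schema <- env$chain$schema
  ptf <- schema_features(schema, groups = "PTF")
  X <- encode_design(record, schema, ptf, env$chain$normalizer)
  stats::setNames(as.numeric(X[1, ]), colnames(X))
}

#' Reset the environment to a fresh synthetic patient
#'
#' Samples one pre-treatment profile from the VAE and returns the
#' flattened observation (no action, post-intervention or outcome fields).
#'
#' @param env A `twin_env`.
#' @param seed Integer seed; the same seed reproduces the same patient.
#' @return A named numeric observation vector.
#' @export
env_reset <- function(env, seed = NULL) {
  patient <- sample_patients(env$vae, 1, seed = seed)
  env$state$record <- patient
  env$state$step_index <- 0L
  env$state$done <- FALSE
  env$state$seed <- seed
  env_observation(env, patient)
}

#' Advance the environment by one treatment decision
#'
#' Actions are integer-coded per step: step 0 and 1 accept `{0, 1}`
#' (no/yes definitive surgery, then induction); step 2 accepts `{0, 1, 2}`
#' (no radiotherapy / radiotherapy / radiotherapy with concurrent
#' chemotherapy). Intermediate steps append the action and fill the
#' stage-appropriate predicted outcomes with reward 0; the final step runs
#' the remaining rollout, sets `done`, and returns the reward. `info`
#' carries the full record.
#'
#' @param env A `twin_env`.
#' @param action Integer action code.
#' @return A list `observation`, `reward`, `done`, `info`.
#' @export
env_step <- function(env, action) {
  st <- env$state
  if (st$done) stop_hnc("episode is done; call env_reset()")
  step <- st$step_index
  feature <- names(STEP_ACTIONS)[step + 1L]
  labels <- STEP_ACTIONS[[step + 1L]]
  if (!is.numeric(action) || length(action) != 1 ||
      !(action %in% (seq_along(labels) - 1L))) {
    stop_hnc("action %s out of range for step %d (expects 0..%d)",
             paste(action, collapse = ","), step, length(labels) - 1L)
  }
  record <- st$record
  record[[feature]] <- labels[action + 1L]
  reward <- 0
  step_seed <- if (is.null(st$seed)) NULL else st$seed + step + 1L

  if (step == 0L) {
    # post-surgical pathology becomes observable right after the decision
    record <- chain_fill(env$chain, record, c("ENE", "Margin"), env$mode)
  } else if (step == 2L) {
    remaining <- setdiff(env$chain$spec$target,
                         c(names(STEP_ACTIONS), "ENE", "Margin"))
    record <- with_seed(step_seed,
                        chain_fill(env$chain, record, remaining, env$mode))
    p_relapse <- attr(record, "relapse_prob")
    burden_cols <- paste0("mdasi_endrt_", env$reward$symptoms)
    burden <- mean(unlist(record[1, burden_cols]), na.rm = TRUE)
    if (is.nan(burden)) burden <- 0  # no radiotherapy: no end-of-RT assessment
    reward <- -env$reward$relapse_weight * p_relapse -
      env$reward$symptom_weight * burden / 10
    st$done <- TRUE
  }
  st$record <- record
  st$step_index <- step + 1L
  list(observation = env_observation(env, record), reward = reward,
       done = st$done, info = record)
}

#' Compare two treatment plans on a shared synthetic population
#'
#' Draws `n_episodes` pre-treatment profiles from the VAE (shared across
#' the two plans, so the comparison is paired and isolates the action
#' effect), rolls each plan out through the chain, and summarises the mean
#' predicted relapse probability and mean predicted end-of-radiotherapy
#' symptom burden per plan.
#'
#' @param vae A trained `twin_vae`.
#' @param chain A fitted `twin_chain`.
#' @param plan_a,plan_b Named action vectors/lists (`definitive`,
#'   `induction`, `radio_chemo`).
#' @param n_episodes Number of paired synthetic patients.
#' @param seed Integer seed.
#' @param mode `"expected"` or `"sampled"` rollout.
#' @param symptoms Symptoms entering the burden summary.
#' @return A `plan_comparison`: summary tibble plus per-patient paired
#'   differences.
#' @export
compare_plans <- function(vae, chain, plan_a, plan_b, n_episodes = 100,
                          seed = 1, mode = "expected", symptoms = SYMPTOMS) {
  patients <- sample_patients(vae, n_episodes, seed = seed)
  burden_cols <- paste0("mdasi_endrt_", symptoms)
  run <- function(plan, offset) {
    rec <- rollout_cohort(chain, patients, plan, mode = mode,
                          seed = if (mode == "sampled") seed + offset else NULL)
    burden <- rowMeans(as.matrix(rec[, burden_cols]), na.rm = TRUE)
    burden[is.nan(burden)] <- 0
    tibble::tibble(relapse_prob = attr(rec, "relapse_prob"), burden = burden)
  }
  a <- run(plan_a, 1000L)
  b <- run(plan_b, 2000L)
  summary <- tibble::tibble(
    plan = c("plan_a", "plan_b"),
    label = c(paste(unlist(plan_a), collapse = "/"),
              paste(unlist(plan_b), collapse = "/")),
    mean_relapse_prob = c(mean(a$relapse_prob), mean(b$relapse_prob)),
    mean_symptom_burden = c(mean(a$burden), mean(b$burden))
  )
  structure(list(summary = summary,
                 paired = tibble::tibble(
                   relapse_diff = a$relapse_prob - b$relapse_prob,
                   burden_diff = a$burden - b$burden),
                 n_episodes = n_episodes, seed = seed, mode = mode),
            class = "plan_comparison")
}

#' @export
print.plan_comparison <- function(x, ...) {
  cat(sprintf("Plan comparison over %d paired synthetic patients (%s mode)\n",
              x$n_episodes, x$mode))
  print(x$summary)
  invisible(x)
}
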