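# Environment tests share one small trained VAE + chain.

env_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- test_schema()
      gen <- generate_cohort(test_params(), 250, seed = 33)
      vae <- train_vae(gen$cohort, sch, vae_config(epochs = 40, seed = 2))
      chain <- suppressWarnings(fit_chain(gen$cohort, sch, seed = 3))
      cache <<- list(vae = vae, chain = chain)
    }
    cache
  }
})

test_that("episodes last exactly three steps and observations are PTF-only", {
  fx <- env_fixture()
  env <- twin_env(fx$vae, fx$chain)
  obs <- env_reset(env, seed = 5)
  expect_false(any(grepl("definitive|induction|radio|ENE|Margin|rt_|relapse",
                         names(obs))))
  obs2 <- env_reset(env, seed = 5)
  expect_identical(obs, obs2)

  env_reset(env, seed = 5)
  s1 <- env_step(env, 0)
  s2 <- env_step(env, 1)
  s3 <- env_step(env, 2)
  expect_false(s1$done); expect_false(s2$done); expect_true(s3$done)
  expect_equal(s1$reward, 0); expect_equal(s2$reward, 0)
  expect_lt(s3$reward, 0)
  expect_error(env_step(env, 0), "done")
})

test_that("illegal actions are range errors", {
  fx <- env_fixture()
  env <- twin_env(fx$vae, fx$chain)
  env_reset(env, seed = 6)
  expect_error(env_step(env, 2), "out of range")  # binary step
  env_reset(env, seed = 6)
  env_step(env, 1); env_step(env, 0)
  expect_error(env_step(env, 3), "out of range")  # ternary step
})

test_that("with zero symptom weight the reward is minus the relapse probability", {
  fx <- env_fixture()
  env <- twin_env(fx$vae, fx$chain,
                  reward = reward_config(relapse_weight = 1, symptom_weight = 0))
  env_reset(env, seed = 7)
  env_step(env, 0); env_step(env, 0)
  s <- env_step(env, 1)
  expect_equal(s$reward, -attr(s$info, "relapse_prob"))
  # reproducible reward ordering for two fixed plans on a fixed seed
  run_plan <- function(a1, a2, a3, seed) {
    env_reset(env, seed = seed)
    env_step(env, a1); env_step(env, a2)
    env_step(env, a3)$reward
  }
  r_cons <- run_plan(0, 0, 1, 11)
  r_aggr <- run_plan(1, 1, 2, 11)
  expect_identical(r_cons, run_plan(0, 0, 1, 11))
  expect_identical(r_aggr, run_plan(1, 1, 2, 11))
})

test_that("paired plan comparison shares patients and is internally consistent", {
  fx <- env_fixture()
  plan <- c(definitive = "no", induction = "no", radio_chemo = "yes")
  same <- compare_plans(fx$vae, fx$chain, plan, plan, n_episodes = 8, seed = 9)
  expect_equal(same$paired$relapse_diff, rep(0, 8))
  expect_equal(same$paired$burden_diff, rep(0, 8))
  expect_equal(same$summary$mean_relapse_prob[1], same$summary$mean_relapse_prob[2])

  one <- compare_plans(fx$vae, fx$chain, plan,
                       c(definitive = "yes", induction = "no",
                         radio_chemo = "no"),
                       n_episodes = 1, seed = 10)
  two <- compare_plans(fx$vae, fx$chain, plan,
                       c(definitive = "yes", induction = "no",
                         radio_chemo = "no"),
                       n_episodes = 1, seed = 10)
  expect_identical(one$summary, two$summary)
})
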