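test_that("ELBO components match the closed forms on crafted inputs", {
  cfg <- vae_config()
  # perfect numeric reconstruction, standard-normal posterior: all zero
  x <- matrix(c(0.3, -1, 2, 0.5), 2, 2)
  out <- elbo_loss(list(numerical = x, categorical = list()),
                   list(numerical = x, categorical = list()),
                   mu = matrix(0, 2, 3), logvar = matrix(0, 2, 3), cfg)
  expect_equal(out$recon_numerical, 0)
  expect_equal(out$kl, 0)
  expect_equal(out$total, 0)

  # scalar latent with mu = 1, logvar = 0: KL = 0.5
  out2 <- elbo_loss(list(numerical = matrix(0, 1, 1), categorical = list()),
                    list(numerical = matrix(0, 1, 1), categorical = list()),
                    mu = matrix(1, 1, 1), logvar = matrix(0, 1, 1), cfg)
  expect_equal(out2$kl, 0.5)

  # one categorical feature, probability 0.25 on the true class
  onehot <- matrix(c(1, 0, 0, 0), 1, 4)
  probs <- matrix(c(0.25, 0.25, 0.25, 0.25), 1, 4)
  out3 <- elbo_loss(list(numerical = NULL, categorical = list(f = onehot)),
                    list(numerical = NULL, categorical = list(f = probs)),
                    mu = matrix(0, 1, 1), logvar = matrix(0, 1, 1), cfg)
  expect_equal(out3$recon_categorical, -log(0.25))

  # kl_weight scales only the KL contribution to the total
  cfg0 <- vae_config(kl_weight = 0)
  out4 <- elbo_loss(list(numerical = matrix(0, 1, 1), categorical = list()),
                    list(numerical = matrix(1, 1, 1), categorical = list()),
                    mu = matrix(1, 1, 1), logvar = matrix(0, 1, 1), cfg0)
  expect_equal(out4$total, out4$recon_numerical)
})

test_that("closed-form KL agrees with a numerical-integration oracle", {
  kl_numeric <- function(mu, sigma) {
    integrand <- function(x) {
      d <- stats::dnorm(x, mu, sigma)
      lr <- stats::dnorm(x, mu, sigma, log = TRUE) - stats::dnorm(x, log = TRUE)
      ifelse(d == 0, 0, d * lr)
    }
    stats::integrate(integrand, mu - 12 * sigma, mu + 12 * sigma,
                     rel.tol = 1e-10)$value
  }
  set.seed(31)
  for (i in 1:12) {
    mu <- rnorm(1, 0, 2)
    sigma <- exp(rnorm(1, 0, 0.7))
    closed <- 0.5 * (mu^2 + sigma^2 - 1 - log(sigma^2))
    expect_equal(closed, kl_numeric(mu, sigma), tolerance = 1e-6)
  }
})

test_that("training reduces the loss and is reproducible", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 300, seed = 21)
  cfg <- vae_config(epochs = 60, seed = 4)
  vae <- train_vae(gen$cohort, sch, cfg)
  expect_lt(dplyr::last(vae$history$total), vae$history$total[1])
  expect_equal(nrow(vae$history), 60)

  vae2 <- train_vae(gen$cohort, sch, cfg)
  expect_identical(dplyr::last(vae$history$total), dplyr::last(vae2$history$total))

  # kl_weight = 0: reconstruction still improves
  vae0 <- train_vae(gen$cohort, sch, vae_config(epochs = 40, kl_weight = 0, seed = 4))
  h <- vae0$history
  expect_lt(dplyr::last(h$recon_numerical + h$recon_categorical),
            h$recon_numerical[1] + h$recon_categorical[1])
})

test_that("sampled patients are schema-legal PTF profiles", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 250, seed = 22)
  vae <- train_vae(gen$cohort, sch, vae_config(epochs = 40, seed = 6))
  synth <- sample_patients(vae, 500, seed = 7)
  expect_equal(nrow(synth), 500)
  expect_setequal(setdiff(names(synth), "patient_id"),
                  sch$name[sch$group == "PTF"])
  expect_equal(nrow(validate_cohort(synth, sch)), 0)
  # integer-valued bounded scores are integers within bounds
  expect_true(all(synth$mdasi_baseline_fatigue %in% 0:10))
  expect_equal(nrow(sample_patients(vae, 0)), 0)
  # argmax mode is deterministic given the latent draw
  a <- sample_patients(vae, 20, seed = 9, mode = "argmax")
  b <- sample_patients(vae, 20, seed = 9, mode = "argmax")
  expect_identical(a, b)
})
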