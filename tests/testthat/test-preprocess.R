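test_that("normalizer uses the population sd convention and inverts exactly", {
  sch <- test_schema()
  co <- tibble::tibble(patient_id = c("a", "b", "c"), age = c(1, 2, 3))
  norm <- fit_normalizer(co, sch)
  z <- apply_normalizer(co, norm)
  # hand-computed under the divide-by-n convention: sd = sqrt(2/3)
  expect_equal(z$age, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z$age), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z$age^2)), 1, tolerance = 1e-8)

  gen <- test_cohort()
  norm2 <- fit_normalizer(gen$cohort, sch)
  round_trip <- invert_normalizer(apply_normalizer(gen$cohort, norm2), norm2)
  for (f in norm2$feature) {
    expect_equal(round_trip[[f]], gen$cohort[[f]], tolerance = 1e-10)
  }
})

test_that("constant columns pass through flagged; all-missing columns error", {
  sch <- test_schema()
  co <- tibble::tibble(patient_id = c("a", "b"), age = c(5, 5))
  expect_warning(norm <- fit_normalizer(co, sch), "constant")
  expect_true(norm$constant[norm$feature == "age"])
  expect_equal(apply_normalizer(co, norm)$age, c(0, 0))

  co2 <- tibble::tibble(patient_id = c("a", "b"), rt_dose = c(NA_real_, NA_real_))
  expect_error(fit_normalizer(co2, sch), "all-missing")
})

test_that("imputation is family-specific", {
  sch <- test_schema()
  co <- test_cohort()$cohort
  # boosted family: untouched, missing preserved
  expect_identical(impute_cohort(co, sch, family = "boosted"), co)

  co2 <- co
  co2$age[1] <- NA
  co2$gender[2] <- NA
  filled <- impute_cohort(co2, sch, family = "vae_mlp", train = co2)
  expect_equal(filled$age[1], mean(co2$age, na.rm = TRUE))
  expect_equal(filled$gender[2], names(which.max(table(co2$gender))))
  # complete data: identity for both families
  complete <- co[, c("patient_id", "age", "gender")]
  expect_identical(impute_cohort(complete, sch, family = "vae_mlp"), complete)
})

test_that("no test-set statistic leaks into the normalizer or imputation", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 300, seed = 55)
  sp <- split_cohort(gen$cohort, seed = 56)
  norm <- fit_normalizer(sp$train, sch)
  # perturb the test rows arbitrarily: fitted parameters must not move
  perturbed <- sp$test
  num <- intersect(names(perturbed), norm$feature)
  for (f in num) perturbed[[f]] <- perturbed[[f]] + 1000
  norm2 <- fit_normalizer(sp$train, sch)
  expect_identical(norm, norm2)

  imp1 <- impute_cohort(sp$test, sch, family = "vae_mlp", train = sp$train)
  co_missing <- sp$test
  co_missing$age[1] <- NA
  imp2 <- impute_cohort(co_missing, sch, family = "vae_mlp", train = sp$train)
  expect_equal(imp2$age[1], mean(sp$train$age))
})

test_that("the split is disjoint, exhaustive, and seed-reproducible", {
  gen <- generate_cohort(test_params(), 676, seed = 61)
  sp <- split_cohort(gen$cohort, seed = 62)
  expect_equal(nrow(sp$train), 539)
  expect_equal(nrow(sp$test), 137)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  gen$cohort$patient_id)
  sp2 <- split_cohort(gen$cohort, seed = 62)
  expect_identical(sp, sp2)
  expect_error(split_cohort(gen$cohort, n_train = 100, n_test = 100), "must equal")
})
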