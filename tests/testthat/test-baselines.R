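test_that("the median/mean baseline is constant and uses coded medians", {
  sch <- test_schema()
  gen <- test_cohort()
  bl <- baseline_median_mean(gen$cohort, sch)
  pred <- hnctwin:::predict_baseline(bl, "radio/chemo", gen$cohort[1:25, ], sch)
  expect_length(unique(pred), 1)
  # numerical targets predict the training mean
  pm <- hnctwin:::predict_baseline(bl, "mdasi_endrt_fatigue", gen$cohort[1:5, ], sch)
  expect_equal(pm[1], mean(gen$cohort$mdasi_endrt_fatigue, na.rm = TRUE))

  # coded median on a crafted label set: codes c(1,1,2,3) -> lower median 1
  co <- gen$cohort[1:4, ]
  co$`radio/chemo` <- c("no", "no", "yes", "yes_with_concurrent_chemotherapy")
  bl2 <- baseline_median_mean(co, sch, targets = "radio/chemo")
  expect_equal(bl2$predictions$`radio/chemo`, "no")
  bl3 <- baseline_median_mean(co, sch, targets = "radio/chemo",
                              mode_categorical = TRUE)
  expect_true(bl3$predictions$`radio/chemo` %in% c("no", "yes"))
})

test_that("constant-mean prediction attains the population variance as MSE", {
  set.seed(4)
  y <- rnorm(5000, 3, 2)
  expect_equal(mse(y, rep(mean(y), length(y))),
               mean((y - mean(y))^2), tolerance = 1e-12)
})

test_that("the random baseline draws proportional to training frequencies", {
  sch <- test_schema()
  gen <- test_cohort()
  bl <- baseline_random(gen$cohort, sch)
  pred <- hnctwin:::predict_baseline(bl, "definitive",
                                     gen$cohort[rep(1, 5000), ], sch, seed = 9)
  p_train <- mean(gen$cohort$definitive == "yes")
  expect_lt(abs(mean(pred == "yes") - p_train), 0.03)

  # expected macro-F1 of random guessing on a balanced binary target is 0.5
  set.seed(10)
  y <- rep(c("a", "b"), each = 500)
  scores <- replicate(60, macro_f1(y, sample(y), c("a", "b")))
  expect_lt(abs(mean(scores) - 0.5), 0.02)
})

test_that("the MLP baseline fits per-node models on imputed normalized data", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 220, seed = 81)
  spec <- default_chain(sch)[c(1, 12), ]  # one classification, one regression
  bl <- suppressWarnings(baseline_mlp(gen$cohort, sch, spec = spec, seed = 2))
  pred_c <- hnctwin:::predict_baseline(bl, spec$target[1], gen$cohort[1:10, ], sch)
  expect_true(all(pred_c %in% c("no", "yes")))
  pred_r <- hnctwin:::predict_baseline(bl, spec$target[2], gen$cohort[1:10, ], sch)
  expect_true(all(is.finite(pred_r)))
})
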