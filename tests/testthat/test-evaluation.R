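test_that("wasserstein_1d matches closed forms and the transport oracle", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(0, 1), 1)
  expect_equal(wasserstein_1d(c(0, 1), c(0, 1, 1)), 1 / 6)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")

  # exhaustive minimum-cost matching oracle on random small samples
  set.seed(17)
  for (i in 1:25) {
    na <- sample(2:6, 1)
    equal <- i %% 2 == 0
    nb <- if (equal) na else sample(2:6, 1)
    a <- round(rnorm(na), 2)
    b <- round(rnorm(nb, 0.5), 2)
    expect_equal(wasserstein_1d(a, b), oracle_w1(a, b), tolerance = 1e-9,
                 label = sprintf("case %d", i))
  }
})

test_that("categorical distance is total variation over declared categories", {
  expect_equal(categorical_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(categorical_distance(rep("a", 4), rep("b", 3)), 1)
  a <- c(rep("x", 6), rep("y", 4))
  b <- c(rep("x", 5), rep("y", 5))
  expect_equal(categorical_distance(a, b), 0.1)
})

test_that("macro_f1 matches hand computations and its invariances", {
  expect_equal(macro_f1(c("a", "a"), c("a", "a")), 1)
  expect_equal(macro_f1(c("a", "a", "b", "b"), c("a", "b", "b", "b")), 11 / 15)
  # declared-but-absent classes pull the average down
  expect_equal(macro_f1(c("a", "a"), c("a", "a"), classes = c("a", "b")), 0.5)
  # renaming invariance
  y1 <- c("a", "b", "a", "b"); p1 <- c("a", "a", "b", "b")
  relabel <- c(a = "z", b = "q")
  expect_equal(macro_f1(y1, p1, c("a", "b")),
               macro_f1(relabel[y1], relabel[p1], c("z", "q")))
  # bounded
  set.seed(3)
  for (i in 1:10) {
    y <- sample(letters[1:3], 30, replace = TRUE)
    p <- sample(letters[1:3], 30, replace = TRUE)
    m <- macro_f1(y, p, letters[1:3])
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("fidelity report averages per-feature distances and behaves under mixing", {
  sch <- test_schema()
  gen <- test_cohort()
  # identical cohorts: zero everywhere
  f0 <- fidelity_report(gen$cohort, gen$cohort, sch)
  expect_equal(f0$mean_distance, 0)
  expect_equal(mean(f0$per_feature$distance), f0$mean_distance)

  # permutation invariance to patient order
  perm <- withr::with_seed(2, sample.int(nrow(gen$cohort)))
  f1 <- fidelity_report(gen$cohort, gen$cohort[perm, ], sch)
  expect_equal(f1$mean_distance, 0)

  # mixing a clearly shifted synthetic sample back toward the real one
  # cannot increase the transport distance
  set.seed(5)
  real <- tibble::tibble(patient_id = sprintf("R%03d", 1:200),
                         age = rnorm(200, 60, 9))
  synth <- tibble::tibble(patient_id = sprintf("S%03d", 1:200),
                          age = rnorm(200, 75, 9))
  mix <- dplyr::bind_rows(real[1:100, ], synth[1:100, ])
  d_synth <- wasserstein_1d(real$age, synth$age)
  d_mix <- wasserstein_1d(real$age, mix$age)
  expect_lt(d_mix, d_synth)
})

test_that("benchmark scores every chain target and rejects empty test sets", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 220, seed = 91)
  sp <- split_cohort(gen$cohort, seed = 92)
  chain <- suppressWarnings(fit_chain(sp$train, sch, seed = 1))
  models <- list(median_mean = baseline_median_mean(sp$train, sch),
                 random = baseline_random(sp$train, sch),
                 xgboost = chain)
  b <- suppressWarnings(benchmark(models, sp$test, sch, seed = 3))
  expect_lte(nrow(b), 25)
  expect_gte(nrow(b), 20)  # targets with zero observed test labels are skipped
  expect_true(all(c("median_mean", "random", "xgboost") %in% names(b)))
  expect_true(all(b$metric[b$feature == "rt_dose"] == "MSE"))
  expect_error(benchmark(models, sp$test[0, ], sch), "empty test")
})
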