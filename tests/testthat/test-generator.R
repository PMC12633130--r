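test_that("default parameters reproduce the printed marginal quantities", {
  p <- test_params()
  expect_equal(unname(p$marginals$age), c(60.49, 8.92))
  expect_equal(sum(p$sequence$prob), 1)
  # most frequent mined pattern: concurrent chemoradiotherapy alone
  i <- match("n/a -> n/a -> radiotherapy (w/ concurrent chemotherapy)",
             p$sequence$pattern)
  expect_equal(p$sequence$prob[i], 398 / 651)
  # category probabilities sum to one
  for (f in c("gender", "t_nominal", "rt_type", "Margin")) {
    expect_equal(sum(p$marginals[[f]]), 1, tolerance = 1e-9)
  }
})

test_that("treatment-sequence sampling decodes patterns and matches frequencies", {
  p <- test_params()
  # decoding of a surgery-then-radiotherapy pattern
  i <- match("definitive surgery -> n/a -> radiotherapy", p$sequence$pattern)
  expect_equal(p$sequence$definitive[i], "yes")
  expect_equal(p$sequence$induction[i], "no")
  expect_equal(p$sequence$radio_chemo[i], "yes")

  draws <- sample_treatment_sequence(p, n = 100000, seed = 3)
  freq <- table(factor(draws$pattern, levels = p$sequence$pattern)) / nrow(draws)
  se <- sqrt(p$sequence$prob * (1 - p$sequence$prob) / nrow(draws))
  expect_true(all(abs(freq - p$sequence$prob) < 3 * se + 1e-12))

  # degenerate one-hot distribution
  p1 <- p
  p1$sequence$prob <- c(1, rep(0, 7))
  one <- sample_treatment_sequence(p1, n = 50, seed = 1)
  expect_equal(unique(one$pattern), p$sequence$pattern[1])
})

test_that("generate_cohort handles n = 0 and is seed-deterministic", {
  p <- test_params()
  empty <- generate_cohort(p, 0, seed = 1)
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(sort(setdiff(names(empty$cohort), "patient_id")),
               sort(p$schema$name))
  expect_error(generate_cohort(p, -1), "n must be")

  a <- generate_cohort(p, 150, seed = 7)
  b <- generate_cohort(p, 150, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(p, 150, seed = 8)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("marginals are recovered at n = 10,000 under the full planted effects", {
  p <- test_params()
  gen <- generate_cohort(p, 10000, seed = 42)
  co <- gen$cohort
  n <- nrow(co)

  # numerical means within 4 sd / sqrt(n) (+ 0.1 clip-and-round allowance
  # for the bounded scores)
  for (f in names(p$marginals)) {
    marg <- p$marginals[[f]]
    if (!is.null(names(marg)) && "mean" %in% names(marg)) {
      x <- co[[f]][!is.na(co[[f]])]
      row <- p$schema[p$schema$name == f, ]
      allow <- 4 * marg[["sd"]] / sqrt(length(x)) +
        if (!is.na(row$lo)) 0.1 else 0
      expect_lt(abs(mean(x) - marg[["mean"]]), allow, label = f)
    }
  }

  # categorical probabilities within 0.02 of their parameters
  for (f in c("gender", "smoking_status", "site_of_tumor", "t_nominal",
              "n_nominal", "p16_hpv_postive", "ENE", "Margin", "rt_type")) {
    probs <- p$marginals[[f]]
    x <- co[[f]][!is.na(co[[f]])]
    obs <- table(factor(x, levels = names(probs))) / length(x)
    expect_lt(max(abs(obs - probs)), 0.02, label = f)
  }

  # action marginals match the sequence-table-derived probabilities
  seq_tab <- p$sequence
  for (f in c("definitive", "induction", "radio/chemo")) {
    col <- sub("radio/chemo", "radio_chemo", f)
    base <- tapply(seq_tab$prob, seq_tab[[col]], sum)
    obs <- table(co[[f]]) / n
    expect_lt(max(abs(obs[names(base)] - base)), 0.02, label = f)
  }

  # relapse prevalence among labelled patients
  expect_lt(abs(mean(co$relapse_yr3 == "True", na.rm = TRUE) - 35 / 188), 0.02)
})

test_that("structural missingness is exact by construction", {
  co <- test_cohort()$cohort
  expect_identical(!is.na(co$ENE), co$definitive == "yes")
  expect_identical(!is.na(co$Margin), co$definitive == "yes")
  expect_identical(!is.na(co$rt_dose), co$`radio/chemo` != "no")
  expect_identical(!is.na(co$rt_type), co$`radio/chemo` != "no")
})

test_that("planted treatment-intensity signal raises end-of-RT symptom burden", {
  gen <- generate_cohort(test_params(), 4000, seed = 9)
  co <- gen$cohort
  agg <- co$`radio/chemo` == "yes_with_concurrent_chemotherapy"
  none <- co$`radio/chemo` == "no"
  burden <- rowMeans(co[, paste0("mdasi_endrt_", c("fatigue", "drymouth",
                                                  "swallow", "taste"))])
  expect_gt(mean(burden[agg]), mean(burden[none]))
  # and lowers true relapse probability
  expect_lt(mean(gen$truth$relapse_prob[agg]), mean(gen$truth$relapse_prob[none]))
})

test_that("patient order carries no information (shuffle invariance)", {
  gen <- generate_cohort(test_params(), 500, seed = 13)
  co <- gen$cohort
  perm <- withr::with_seed(1, sample.int(nrow(co)))
  shuffled <- co[perm, ]
  expect_equal(mean(shuffled$age), mean(co$age))
  expect_equal(table(shuffled$t_nominal), table(co$t_nominal))
})

test_that("zero_effects removes every planted dependency", {
  p0 <- zero_effects(test_params())
  expect_true(all(unlist(p0$effects) == 0))
  gen <- generate_cohort(p0, 3000, seed = 5)
  co <- gen$cohort
  # with effects off, relapse probability is constant
  expect_equal(length(unique(gen$truth$relapse_prob)), 1)
  # and symptom burden no longer tracks treatment intensity
  agg <- co$`radio/chemo` == "yes_with_concurrent_chemotherapy"
  none <- co$`radio/chemo` == "no"
  d <- mean(co$mdasi_endrt_fatigue[agg]) - mean(co$mdasi_endrt_fatigue[none])
  expect_lt(abs(d), 0.4)
})
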