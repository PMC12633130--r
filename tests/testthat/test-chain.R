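test_that("the default chain orders every non-PTF feature after its ancestors", {
  sch <- test_schema()
  spec <- default_chain(sch)
  ptf <- sch$name[sch$group == "PTF"]
  expect_equal(nrow(spec), sum(sch$group != "PTF"))
  expect_equal(nrow(spec), 25)

  # first action conditions on PTF only
  expect_setequal(spec$parents[[match("definitive", spec$target)]], ptf)
  # the final relapse node conditions on every other modelled feature
  rel_parents <- spec$parents[[match("relapse_yr3", spec$target)]]
  expect_setequal(rel_parents, setdiff(sch$name, "relapse_yr3"))
  # radiotherapy dose is a regression node
  expect_equal(spec$task[spec$target == "rt_dose"], "regression")
  # acyclicity: parents strictly precede their target
  for (i in seq_len(nrow(spec))) {
    expect_false(spec$target[i] %in% spec$parents[[i]])
    later <- spec$target[seq_len(nrow(spec)) > i]
    expect_length(intersect(spec$parents[[i]], later), 0)
  }
})

test_that("balanced class weights equalize per-class totals", {
  y <- c(rep("a", 90), rep("b", 10))
  w <- hnctwin:::balanced_weights(y)
  # minority weight / majority weight = 9
  expect_equal(w[y == "b"][1] / w[y == "a"][1], 9)
  expect_equal(sum(w[y == "a"]), sum(w[y == "b"]), tolerance = 1e-9)
})

test_that("a one-point grid skips the search and still fits", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 250, seed = 71)
  norm <- fit_normalizer(gen$cohort, sch)
  grid1 <- grid_config("fast")$boosted[1, ]
  node <- fit_node(gen$cohort, sch, "definitive",
                   sch$name[sch$group == "PTF"], grid1, normalizer = norm)
  expect_true(is.na(node$cv_score))
  expect_equal(node$best_params$learning_rate, grid1$learning_rate)
  pred <- predict_node(structure(list(schema = sch, normalizer = norm,
                                      nodes = list(definitive = node),
                                      spec = default_chain(sch)),
                                 class = "twin_chain"),
                       "definitive", gen$cohort)
  expect_true(all(pred %in% c("no", "yes")))
})

test_that("cross-validated grid search recovers planted signal above chance", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 539, seed = 72)
  norm <- fit_normalizer(gen$cohort, sch)
  grid2 <- grid_config("fast")$boosted_regression  # two-point grid forces CV
  grid2$max_depth <- c(3L, 4L)
  node <- fit_node(gen$cohort, sch, "radio/chemo",
                   sch$name[sch$group == "PTF"], grid2,
                   normalizer = norm, seed = 3)
  expect_false(is.na(node$cv_score))
  # the random baseline's expected macro-F1 equals the mean class frequency
  p <- table(gen$cohort$`radio/chemo`) / nrow(gen$cohort)
  expect_gt(node$cv_score, mean(p))
})

test_that("single observed class degenerates to a constant predictor", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 120, seed = 73)
  co <- gen$cohort
  co$relapse_yr3[!is.na(co$relapse_yr3)] <- "False"
  norm <- fit_normalizer(co, sch)
  expect_warning(
    node <- fit_node(co, sch, "relapse_yr3", "age",
                     grid_config("fast")$boosted, normalizer = norm),
    "single|constant|observed class")
  expect_equal(node$constant, "False")
})

test_that("chain refits are deterministic and rollouts respect structure", {
  sch <- test_schema()
  gen <- generate_cohort(test_params(), 250, seed = 74)
  chain <- fit_chain(gen$cohort, sch, seed = 2)
  expect_length(chain$nodes, 25)

  chain2 <- fit_chain(gen$cohort, sch, seed = 2)
  probe <- gen$cohort[1:10, ]
  expect_equal(predict_node(chain, "mdasi_endrt_fatigue", probe),
               predict_node(chain2, "mdasi_endrt_fatigue", probe))

  ptf_cols <- c("patient_id", sch$name[sch$group == "PTF"])
  ptf_row <- gen$cohort[1, ptf_cols]
  # no radiotherapy: all rt_* fields stay missing; no surgery: no pathology
  r <- rollout(chain, ptf_row,
               c(definitive = "no", induction = "no", radio_chemo = "no"))
  expect_true(is.na(r$rt_type) && is.na(r$rt_dose) && is.na(r$rt_fraction))
  expect_true(is.na(r$ENE) && is.na(r$Margin))
  expect_equal(nrow(validate_cohort(r, sch)), 0)

  # expected mode is deterministic
  r2 <- rollout(chain, ptf_row,
                c(definitive = "no", induction = "no", radio_chemo = "no"))
  expect_identical(as.data.frame(r), as.data.frame(r2))

  # surgery opens the pathology nodes
  r3 <- rollout(chain, ptf_row,
                c(definitive = "yes", induction = "no", radio_chemo = "yes"))
  expect_false(is.na(r3$ENE))
  expect_false(is.na(r3$rt_dose))
  expect_true(is.finite(attr(r3, "relapse_prob")))

  expect_error(rollout(chain, ptf_row,
                       c(definitive = "sometimes", induction = "no",
                         radio_chemo = "no")),
               "unknown label")

  # sampled mode draws legal values within bounds
  r4 <- rollout(chain, ptf_row,
                c(definitive = "no", induction = "no",
                  radio_chemo = "yes_with_concurrent_chemotherapy"),
                mode = "sampled", seed = 8)
  expect_equal(nrow(validate_cohort(r4, sch)), 0)
  expect_true(r4$mdasi_endrt_fatigue >= 0 && r4$mdasi_endrt_fatigue <= 10)
})
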