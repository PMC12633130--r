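# The two bundled case-study timelines are the worked examples: a short
# concurrent-chemoradiotherapy course with early relapse, and a prolonged
# multi-modal history with recurrences.

test_that("proximal chemotherapy and radiation merge into one concurrent action", {
  cycles <- segment_cycles(patient_case_log(1), merge_window_days = 45)
  expect_length(cycles, 1)
  expect_equal(nrow(cycles[[1]]$actions), 1)
  expect_equal(cycles[[1]]$actions$procedure,
               "radiotherapy (w/ concurrent chemotherapy)")
  expect_true(cycles[[1]]$statuses$relapse[1])
})

test_that("a multi-cycle history segments at relapses and new action runs", {
  cycles <- suppressWarnings(segment_cycles(patient_case_log(2)))
  expect_gte(length(cycles), 5)
  # first cycle: radiation day 53; statuses NED day 168 then relapse day 830
  expect_equal(cycles[[1]]$actions$day, 53)
  expect_equal(cycles[[1]]$statuses$day, c(168, 830))
  # every action event lands in exactly one cycle
  n_actions <- sum(vapply(cycles, function(cy) nrow(cy$actions), integer(1)))
  log2 <- patient_case_log(2)
  # the concurrent merge does not apply here (no chemo+radiation pair in
  # one cycle within the window), so counts match the raw log
  expect_equal(n_actions, sum(log2$category == "Action"))
})

test_that("single-cycle simplification reproduces the two case studies", {
  r1 <- simplify_to_single_cycle(segment_cycles(patient_case_log(1)))
  expect_equal(r1$radio_chemo, "yes_with_concurrent_chemotherapy")
  expect_equal(r1$definitive, "no")
  expect_equal(r1$relapse_yr3, "True")  # relapse day 517 <= 1095

  r2 <- simplify_to_single_cycle(suppressWarnings(
    segment_cycles(patient_case_log(2))))
  expect_equal(r2$radio_chemo, "yes")
  expect_equal(r2$status_yr3, "No Evidence of Disease (NED)")  # day 1113
})

test_that("degenerate logs are handled", {
  start_only <- tibble::tibble(day = 0, category = "TreatmentStart",
                               procedure = "Treatment Start")
  expect_length(segment_cycles(start_only), 0)
  expect_error(simplify_to_single_cycle(list()), "no cycles")

  surgery_only <- tibble::tibble(
    day = c(0, 10), category = c("TreatmentStart", "Action"),
    procedure = c("Treatment Start", "Surgery"))
  r <- simplify_to_single_cycle(segment_cycles(surgery_only))
  expect_equal(r$definitive, "yes")
  expect_equal(r$induction, "no")
  expect_equal(r$radio_chemo, "no")
  expect_true(is.na(r$relapse_yr3))

  before <- tibble::tibble(
    day = c(0, 5, 30), category = c("TreatmentStart", "Status", "Action"),
    procedure = c("Treatment Start", "Stable Disease", "Radiation Therapy"))
  expect_warning(cycles <- segment_cycles(before), "precedes")
  expect_equal(cycles[[1]]$statuses$day, 5)
})

test_that("simplification ignores status events after the horizon", {
  base <- tibble::tibble(
    day = c(0, 10, 400), category = c("TreatmentStart", "Action", "Status"),
    procedure = c("Treatment Start", "Radiation Therapy",
                  "No Evidence of Disease (NED)"))
  late <- dplyr::bind_rows(base, tibble::tibble(
    day = 3000, category = "Status", procedure = "Relapse/Recurrence"))
  r_base <- simplify_to_single_cycle(segment_cycles(base))
  r_late <- simplify_to_single_cycle(segment_cycles(late))
  # a relapse far past the horizon does not flip the year-3 outcome
  expect_false(identical(r_late$relapse_yr3, "True"))
  expect_equal(r_base$radio_chemo, r_late$radio_chemo)
})

test_that("elapsed_months uses the mean month length", {
  expect_equal(elapsed_months(28, 517), 16L)
  expect_equal(elapsed_months(100, 100), 0L)
  expect_equal(elapsed_months(0, 3044), 100L)
  expect_error(elapsed_months(10, 5), "day_b")
})

test_that("pattern mining counts triples and matches planted assignments", {
  # degenerate: identical records collapse to one row
  rec <- tibble::tibble(definitive = "no", induction = "no",
                        radio_chemo = "yes")[rep(1, 12), ]
  out <- mine_sequence_patterns(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$count, 12L)
  expect_equal(out$pattern, "n/a -> n/a -> radiotherapy")

  # counts sum to the number of records and match planted truth exactly
  gen <- test_cohort()
  recs <- dplyr::rename(gen$cohort[, c("definitive", "induction", "radio/chemo")],
                        radio_chemo = "radio/chemo")
  mined <- mine_sequence_patterns(recs)
  expect_equal(sum(mined$count), nrow(recs))
  truth_counts <- sort(table(gen$truth$pattern), decreasing = TRUE)
  expect_equal(sort(mined$count, decreasing = TRUE),
               unname(sort(as.integer(truth_counts), decreasing = TRUE)))
  expect_setequal(mined$pattern, names(truth_counts))
})
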