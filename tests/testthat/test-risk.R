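test_that("risk ratio and Katz interval reproduce hand-verified values", {
  # frozen from direct evaluation of the log-method formulas
  r <- risk_ratio(two_by_two(167, 704, 57, 581))
  expect_equal(r$rr, 2.1461, tolerance = 1e-4)
  expect_equal(r$ci_low, 1.6175, tolerance = 1e-4)
  expect_equal(r$ci_high, 2.8474, tolerance = 1e-4)
  expect_lt(r$p_value, 0.001)

  r <- risk_ratio(two_by_two(124, 382, 65, 883))
  expect_equal(r$rr, 3.5741, tolerance = 1e-4)
  expect_equal(r$ci_low, 2.7011, tolerance = 1e-4)
  expect_equal(r$ci_high, 4.7293, tolerance = 1e-4)

  # identical prevalences: RR 1, CI symmetric on the log scale
  r <- risk_ratio(two_by_two(10, 90, 10, 90))
  expect_equal(r$rr, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high))
  expect_gt(r$p_value, 0.99)
})

test_that("cell scaling preserves the estimate and narrows the CI", {
  base <- risk_ratio(two_by_two(12, 40, 7, 55))
  for (k in c(2, 5, 10)) {
    scaled <- risk_ratio(two_by_two(12 * k, 40 * k, 7 * k, 55 * k))
    expect_equal(scaled$rr, base$rr)
    expect_lt(scaled$ci_high - scaled$ci_low, base$ci_high - base$ci_low)
    expect_true(scaled$ci_low <= scaled$rr && scaled$rr <= scaled$ci_high)
  }
})

test_that("swapping the bands inverts the risk ratio", {
  a <- risk_ratio(two_by_two(167, 704, 57, 581))
  b <- risk_ratio(two_by_two(57, 581, 167, 704))
  expect_equal(b$rr, 1 / a$rr)
  expect_equal(b$ci_low, 1 / a$ci_high)
  expect_equal(b$ci_high, 1 / a$ci_low)
})

test_that("zero event cells error by default; correction opts in", {
  expect_error(risk_ratio(two_by_two(0, 10, 5, 10)), "correction")
  expect_error(risk_ratio(two_by_two(5, 10, 0, 10)), "correction")
  r <- risk_ratio(two_by_two(0, 10, 5, 10), correction = TRUE)
  expect_true(is.finite(r$rr) && r$rr > 0)
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
})

test_that("ACT linkage window is inclusive at +/- 14 days", {
  enroll <- as.Date("2022-03-07")
  scored <- mk_scored("P1", rep("NORMAL", 3), c(70, 40, 55),
                      day = c(0, 14, 15))
  scored$normalized_score <- scored$final_score - 50
  act <- mk_act("P1", enroll + 14, 22) # sessions at days 0, 14, 15
  # day 0 is exactly 14 days before: included; day 15 within; day 0..15 all in
  link <- act_linkage(act, scored, analysis_config())
  expect_equal(link$n_window, 3)
  expect_equal(link$time_averaged_score, mean(c(70, 40, 55)))
  expect_equal(link$control_level, "WELL")

  # boundary: session exactly 14 days before only
  act2 <- mk_act("P1", enroll + 29, 12)  # window [15, 43] -> day 15 only
  link2 <- act_linkage(act2, scored, analysis_config())
  expect_equal(link2$n_window, 1)
  expect_equal(link2$band, "LOW")
  expect_equal(link2$control_level, "POOR")

  # empty window -> ineligible
  act3 <- mk_act("P1", enroll + 60, 18)
  link3 <- act_linkage(act3, scored, analysis_config())
  expect_false(link3$eligible)
  expect_true(is.na(link3$time_averaged_score))

  # single score 70 at raw threshold 65 -> HIGH
  act4 <- mk_act("P1", enroll, 22)
  link4 <- act_linkage(act4, mk_scored("P1", "NORMAL", 70, day = 1),
                       analysis_config())
  expect_equal(link4$band, "HIGH")
})

test_that("ACT contrasts reproduce hand-verified prevalence ratios", {
  linkages <- tibble::tibble(
    participant_id = "x", act_date = as.Date("2022-01-01"),
    act_score = 1L,
    control_level = rep(c("POOR", "NOT_WELL", "WELL"),
                        times = c(111, 46, 44)),
    band = c(rep(c("HIGH", "LOW"), c(61, 50)),
             rep(c("HIGH", "LOW"), c(22, 24)),
             rep(c("HIGH", "LOW"), c(18, 26))),
    n_window = 1L, time_averaged_score = 1, eligible = TRUE
  )
  tabs <- act_risk_tables(linkages)
  expect_equal(tabs$POOR$rr, 1.1737, tolerance = 1e-4)
  expect_equal(tabs$POOR$ci_low, 0.9594, tolerance = 1e-4)
  expect_equal(tabs$POOR$ci_high, 1.4358, tolerance = 1e-4)
  expect_equal(tabs$POOR$p_value, 0.1195, tolerance = 1e-3)
  expect_equal(tabs$NOT_WELL$rr, 1.1458, tolerance = 1e-4)

  # degenerate: all assessments well controlled
  all_well <- linkages[linkages$control_level == "WELL", ]
  expect_error(act_risk_tables(all_well), "correction|undefined|zero")
})

test_that("state risk tables exclude the third state and band correctly", {
  scored <- dplyr::bind_rows(
    mk_scored("P1", rep("EXACERBATION", 30), rep(c(70, 60), c(20, 10))),
    mk_scored("P2", rep("MILD", 40), rep(c(70, 60), c(15, 25))),
    mk_scored("P3", rep("NORMAL", 50), rep(c(70, 60), c(10, 40)))
  )
  tabs <- state_risk_tables(scored, analysis_config())
  ex <- tabs$EXACERBATION$table
  expect_equal(c(ex$event_high, ex$nonevent_high, ex$event_low,
                 ex$nonevent_low), c(20, 10, 10, 40))
  mi <- tabs$MILD$table
  expect_equal(c(mi$event_high, mi$nonevent_high, mi$event_low,
                 mi$nonevent_low), c(15, 10, 25, 40))

  # all-normal input hits the zero-cell error path
  expect_error(
    state_risk_tables(mk_scored("P1", rep("NORMAL", 10), rep(60, 10)),
                      analysis_config()),
    "correction"
  )
})

test_that("stratified risk reduces to the pooled table for one stratum and
           flags undefined strata", {
  scored <- dplyr::bind_rows(
    mk_scored("P1", rep(c("EXACERBATION", "MILD", "NORMAL"), c(10, 4, 30)),
              rep(c(70, 60, 70, 60, 70, 60), c(7, 3, 2, 2, 10, 20))),
    mk_scored("P2", rep("NORMAL", 20), rep(c(70, 60), 10))
  )
  one <- stratified_risk(scored, analysis_config(),
                         tibble::tibble(participant_id = c("P1", "P2"),
                                        stratum = "all"))
  pooled <- state_risk_tables(scored, analysis_config())$EXACERBATION
  expect_equal(one$results$rr, pooled$rr)
  expect_equal(dim(one$overlap), c(1, 1))

  two <- stratified_risk(scored, analysis_config(),
                         tibble::tibble(participant_id = c("P1", "P2"),
                                        stratum = c("a", "b")))
  expect_true(two$results$defined[two$results$stratum == "a"])
  expect_false(two$results$defined[two$results$stratum == "b"])
  expect_true(is.na(two$overlap["a", "b"]))
  expect_error(
    stratified_risk(scored, analysis_config(),
                    tibble::tibble(participant_id = c("P1", "P1"),
                                   stratum = c("a", "b"))),
    "exactly one"
  )
})
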