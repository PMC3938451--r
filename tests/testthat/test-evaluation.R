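test_that("confusion tables cross-tabulate and transpose correctly", {
  ct <- confusion_from_labels(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(ct[c("tp", "fn", "fp", "tn")]), c(tp = 2, fn = 0, fp = 0, tn = 2))

  comp <- confusion_from_labels(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(comp$tp, 0); expect_equal(comp$tn, 0)

  set.seed(1)
  p <- runif(50) > 0.5; t <- runif(50) > 0.5
  a <- confusion_from_labels(p, t); b <- confusion_from_labels(t, p)
  expect_equal(a$tp, b$tp); expect_equal(a$tn, b$tn)
  expect_equal(a$fp, b$fn); expect_equal(a$fn, b$fp)
  expect_equal(a$tp + a$fn + a$fp + a$tn, 50)  # margin conservation

  expect_error(confusion_from_labels(c(1, 0), c(1)), "length")
  expect_error(confusion_from_labels(c(1, NA), c(1, 0)), "missing")
})

test_that("sensitivity and specificity are exact rationals with safe edges", {
  ss <- sensitivity_specificity(confusion_table(1, 0, 0, 1))
  expect_equal(ss$sensitivity$value, 1)
  expect_equal(ss$specificity$value, 1)

  undef <- sensitivity_specificity(confusion_table(0, 0, 1, 4))
  expect_true(is.na(undef$sensitivity$value))
  expect_equal(undef$specificity$value, 0.8)

  ss2 <- sensitivity_specificity(confusion_table(50, 35, 1, 99))
  expect_identical(ss2$sensitivity$value, 50 / 85)
  expect_identical(ss2$specificity$numerator, 99)
})

test_that("presentation rounding is half-up, as in printed tables", {
  expect_equal(round_half_up(0.585, 2), 0.59)
  expect_equal(round_half_up(0.125, 2), 0.13)  # round() would give 0.12
  expect_equal(round_half_up(58.82, 1), 58.8)
})

test_that("packaged fixtures reproduce the printed contingency statistics", {
  t2 <- sensitivity_specificity(fixture_confusion(load_study_fixture("table2")))
  expect_equal(round_half_up(t2$sensitivity$value), 0.59)
  expect_equal(round_half_up(t2$specificity$value), 0.99)
  expect_equal(t2$sensitivity$denominator, 85)

  t4 <- sensitivity_specificity(fixture_confusion(load_study_fixture("table4")))
  expect_equal(round_half_up(t4$sensitivity$value), 0.60)
  expect_equal(round_half_up(t4$specificity$value), 0.94)

  t5 <- sensitivity_specificity(fixture_confusion(load_study_fixture("table5")))
  expect_equal(round_half_up(t5$sensitivity$value), 0.99)
  expect_equal(round_half_up(t5$specificity$value), 0.99)

  stats <- study_fixture_statistics()
  get <- function(nm) stats$value[stats$name == nm]
  expect_equal(get("paroxysmal_first_hour_sensitivity"), 37 / 70)
  expect_equal(get("paroxysmal_sinus_first_hour_first_hour_sensitivity"), 23 / 54)
  expect_equal(get("post_episode_hour_1"), 7 / 9)
  expect_equal(get("chronic_holter_detection_full"), 16 / 19)
})

test_that("first-hour patient statistics count flags and exclusions correctly", {
  results <- list(
    stub_patient("a", "PAROXYSMAL", c("PAF_RISK", "NO_RISK")),
    stub_patient("b", "PAROXYSMAL", c("NO_RISK", "PAF_RISK")),
    stub_patient("c", "CHRONIC", c("AF", "AF")),
    stub_patient("d", "HEALTHY", c("NO_RISK", "NO_RISK")),
    stub_patient("e", "HEALTHY", c("PAF_RISK", "NO_RISK")),
    stub_patient("f", "PAROXYSMAL", c("NOT_ANALYZABLE", "NOT_ANALYZABLE")))
  ss <- first_hour_patient_stats(results)
  expect_equal(ss$sensitivity$numerator, 2)   # a and c; b negative, f excluded
  expect_equal(ss$sensitivity$denominator, 3)
  expect_equal(ss$specificity$numerator, 1)
  expect_equal(ss$specificity$denominator, 2)

  healthy_only <- first_hour_patient_stats(results[4:5], case_groups = "NONE")
  expect_true(is.na(healthy_only$sensitivity$value))
})

test_that("post-episode sensitivity tracks the k-th sinus hour", {
  ann <- data.frame(start_ms = c(0, 3.6e6, 5.4e6),
                    end_ms = c(3.6e6, 5.4e6, 6 * 3.6e6),
                    kind = c("SINUS", "AF", "SINUS"))
  flagged <- stub_patient("a", "PAROXYSMAL",
                          c("NO_RISK", "AF", "PAF_RISK", "PAF_RISK", "NO_RISK", "NO_RISK"),
                          annotations = ann)
  unflagged <- stub_patient("b", "PAROXYSMAL",
                            c("NO_RISK", "AF", "NO_RISK", "NO_RISK", "NO_RISK", "NO_RISK"),
                            annotations = ann)
  no_episode <- stub_patient("c", "HEALTHY", rep("NO_RISK", 6))

  r <- list(flagged, unflagged, no_episode)
  h1 <- post_episode_hour_sensitivity(r, 1)
  expect_equal(h1$numerator, 1); expect_equal(h1$denominator, 2)
  h2 <- post_episode_hour_sensitivity(r, 2)
  expect_equal(h2$numerator, 1)
  h3 <- post_episode_hour_sensitivity(r, 3)
  expect_equal(h3$numerator, 0)
  expect_true(is.na(post_episode_hour_sensitivity(list(no_episode), 1)$value))
})

test_that("Holter detection rates count annotated manifest AF per window", {
  ann_af <- data.frame(start_ms = 2 * 3.6e6, end_ms = 2.5 * 3.6e6, kind = "AF")
  results <- list(
    stub_patient("a", "PAROXYSMAL", rep("NO_RISK", 4), annotations = ann_af),
    stub_patient("b", "PAROXYSMAL", rep("NO_RISK", 4)),
    stub_patient("c", "HEALTHY", rep("NO_RISK", 4)))
  full <- holter_detection_rate(results, "PAROXYSMAL", "full")
  expect_equal(full$value, 1 / 2)
  fh <- holter_detection_rate(results, "PAROXYSMAL", "first_hour")
  expect_equal(fh$numerator, 0)
  expect_equal(holter_detection_rate(results, "HEALTHY", "full")$value, 0)
  expect_true(is.na(holter_detection_rate(results, "CHRONIC", "full")$value))
})
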