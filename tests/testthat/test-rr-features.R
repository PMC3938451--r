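test_that("build_rr derives intervals and NN flags from beat labels", {
  b <- beat_series(c(0, 800, 1600))
  rr <- build_rr(b)
  expect_equal(rr$interval_ms, c(800, 800))
  expect_equal(rr$is_nn, c(TRUE, TRUE))

  bv <- beat_series(c(0, 600, 1600), label = c("N", "V", "N"))
  expect_equal(build_rr(bv)$is_nn, c(FALSE, FALSE))

  expect_error(build_rr(beat_series(0)), "no intervals")
})

test_that("Poincare descriptors handle degenerate and alternating series", {
  const <- rr_from_intervals(rep(800, 100))
  pc <- poincare_descriptors(const)
  expect_equal(pc$sd1_ms, 0)
  expect_equal(pc$sd2_ms, 0)
  expect_false(is.finite(pc$sd_ratio))

  alt <- rr_from_intervals(rep(c(600, 800), 50))
  pa <- poincare_descriptors(alt)
  expect_equal(pa$sd1_ms, 200 / sqrt(2), tolerance = 1e-3)
  expect_lt(pa$sd2_ms, 1)

  short <- rr_from_intervals(c(800, 810))
  expect_true(is.na(poincare_descriptors(short)$sd1_ms))
})

test_that("Poincare SD1 approximates the delta-RR closed form on sinus-like data", {
  for (s in 1:5) {
    set.seed(s)
    iv <- 800 + cumsum(rnorm(300, 0, 5)) + rnorm(300, 0, 20)
    pc <- poincare_descriptors(rr_from_intervals(iv))
    x <- iv[-length(iv)]; y <- iv[-1]
    d <- x - y
    sd1_direct <- sqrt(mean((d - mean(d))^2)) / sqrt(2)
    expect_equal(pc$sd1_ms, sd1_direct, tolerance = 0.02)
  }
})

test_that("normalized RR differences follow the printed formula and stay bounded", {
  one <- normalized_rr_differences(rr_from_intervals(c(600, 800)))
  expect_equal(one$values, (600 - 800) / (600 + 800))

  expect_equal(normalized_rr_differences(rr_from_intervals(c(800, 800)))$values, 0)

  set.seed(7)
  iv <- exp(rnorm(200, log(700), 0.4))
  d <- normalized_rr_differences(rr_from_intervals(iv))
  expect_true(all(d$values > -1 & d$values < 1))
  expect_equal(d$dnorm_sd, sd(d$values))
  expect_equal(d$dnorm_p95, unname(quantile(abs(d$values), 0.95)))
})

test_that("extreme-window ratio finds the max-sum run", {
  expect_equal(extreme_window_ratio(rr_from_intervals(rep(700, 20)), 6), 1)
  rr <- rr_from_intervals(c(600, 900, 1000, 950, 980, 1000, 900, 600))
  expect_equal(extreme_window_ratio(rr, 6), 0.9)
  expect_true(is.na(extreme_window_ratio(rr_from_intervals(rep(800, 4)), 6)))

  # non-NN intervals break the runs
  b <- beat_series(cumsum(c(0, rep(800, 12))),
                   label = c(rep("N", 6), "V", rep("N", 6)))
  expect_equal(extreme_window_ratio(build_rr(b), 6), NA_real_)
})

test_that("approximate entropy matches its conventions", {
  expect_equal(approximate_entropy(rep(800, 100)), 0)
  set.seed(11)
  x <- rnorm(120)
  expect_equal(approximate_entropy(x),
               naive_apen(x, 2, 0.2 * sd(x)), tolerance = 1e-10)
  # precondition on NN count for rr input
  expect_true(is.na(approximate_entropy(rr_from_intervals(rep(800, 30)))))
})

test_that("PAC census types complexes by coupling interval and pause", {
  ctx <- function(mid) rr_beats(rr_from_intervals(c(rep(800, 10), mid, rep(800, 10))))
  type_of <- function(mid) {
    r <- pac_census(ctx(mid))$records
    if (!nrow(r)) "none" else r$type
  }
  expect_equal(type_of(c(560, 1040)), "FULL_COMPENSATORY")  # CI+P = 2 NN
  expect_equal(type_of(c(560, 880)), "SINUS_RESET")         # P about NN
  expect_equal(type_of(c(400, 400)), "INTERPOLATED")        # CI+P = NN
  expect_equal(type_of(c(400, 960)), "DELAYED_RESET")       # long pause, CI+P < 1.8 NN

  pc <- pac_census(ctx(c(400, 400)))
  expect_equal(pc$pac_total, 1L)  # the resuming sinus beat is not re-counted
  expect_equal(pc$pac_countable, 1L)

  reset <- pac_census(ctx(c(560, 880)))
  expect_equal(reset$pac_countable, 0L)
  expect_false(reset$records$countable)

  # non-premature beats are never PACs
  expect_equal(pac_census(rr_beats(rr_from_intervals(rep(800, 30))))$pac_total, 0L)
})

test_that("feature vector carries explicit missingness and artifact fraction", {
  frag <- beat_series(seq(0, by = 800, length.out = 30))
  fv <- feature_vector(frag)
  expect_true(is.na(fv$apen))
  expect_lte(fv$nn_count, 29)

  hour <- healthy_snip_beats(3.6e6, seed = 5)
  art <- mark_artifacts(hour, 0.10, seed = 6)
  fva <- feature_vector(art)
  expect_equal(fva$artifact_fraction, 0.10, tolerance = 0.02)
  expect_false(anyNA(fva[c("sd1_ms", "sd2_ms", "dnorm_sd",
                           "extreme_window_ratio", "apen")]))
  expect_equal(fva$pac_countable <= fva$pac_total, TRUE)
})

test_that("features transform correctly under translation and scaling", {
  b <- healthy_snip_beats(1.2e6, seed = 9)
  fv <- feature_vector(b)
  shifted <- beat_series(b$time_ms + 123456, b$label, b$width_ms,
                         b$amplitude_mv, b$shape_corr)
  fs <- feature_vector(shifted)
  for (col in c("sd1_ms", "sd2_ms", "dnorm_sd", "extreme_window_ratio", "apen"))
    expect_equal(fs[[col]], fv[[col]])

  iv <- build_rr(b)$interval_ms
  rr2 <- rr_from_intervals(2 * iv)
  p1 <- poincare_descriptors(build_rr(b))
  p2 <- poincare_descriptors(rr2)
  expect_equal(p2$sd1_ms, 2 * p1$sd1_ms, tolerance = 1e-12)
  expect_equal(p2$sd2_ms, 2 * p1$sd2_ms, tolerance = 1e-12)
  expect_equal(normalized_rr_differences(rr2)$dnorm_sd,
               normalized_rr_differences(rr_from_intervals(iv))$dnorm_sd)
  expect_equal(extreme_window_ratio(rr2, 6),
               extreme_window_ratio(rr_from_intervals(iv), 6))
})

test_that("feature tables survive a CSV round trip", {
  b <- healthy_snip_beats(1.2e6, seed = 13)
  fv <- feature_vector(b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fv, path)
  back <- read_features_csv(path)
  expect_equal(back$sd1_ms, fv$sd1_ms)
  expect_equal(back$pac_countable, fv$pac_countable)
})
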