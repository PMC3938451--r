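test_that("sinus generator hits its statistical targets and is seeded", {
  rr <- gen_sinus_rr(3.6e6, 800, 40, seed = 1)
  expect_equal(mean(rr$interval_ms), 800, tolerance = 0.02)
  expect_equal(sd(rr$interval_ms), 40, tolerance = 0.15)

  expect_true(all(gen_sinus_rr(6e5, 800, 0, seed = 2)$interval_ms == 800))

  a <- gen_sinus_rr(6e5, 800, 40, seed = 3)
  b <- gen_sinus_rr(6e5, 800, 40, seed = 3)
  expect_identical(a$interval_ms, b$interval_ms)
  expect_false(identical(a$interval_ms,
                         gen_sinus_rr(6e5, 800, 40, seed = 4)$interval_ms))
})

test_that("AF generator is uncorrelated, heavy, and faster than sinus", {
  af <- gen_af_rr(3.6e6, 600, 0.2, seed = 5)
  cv <- sd(af$interval_ms) / mean(af$interval_ms)
  expect_gte(cv, 0.17); expect_lte(cv, 0.23)
  n <- nrow(af)
  expect_gt(n, 1000)
  lag1 <- cor(af$interval_ms[-1], af$interval_ms[-n])
  expect_gt(lag1, -0.1); expect_lt(lag1, 0.1)

  # irregularity dominates a matched sinus snip
  for (s in 1:3) {
    dn_af <- feature_vector(af_snip_beats(1.8e6, seed = 50 + s))$dnorm_sd
    dn_si <- feature_vector(healthy_snip_beats(1.8e6, seed = 60 + s))$dnorm_sd
    expect_gte(dn_af / dn_si, 3)
  }
  expect_identical(gen_af_rr(6e5, 600, 0.2, seed = 6)$interval_ms,
                   gen_af_rr(6e5, 600, 0.2, seed = 6)$interval_ms)
})

test_that("AF entropy exceeds matched-mean sinus entropy across seeds", {
  # compared at snip scale: with the per-series tolerance the ApEn estimate
  # needs hour-length series before the AF/sinus complexity gap stabilizes
  wins <- vapply(1:20, function(s) {
    af <- gen_af_rr(3.6e6, 600, 0.2, seed = s)$interval_ms
    si <- gen_sinus_rr(3.6e6, 600, 40, seed = 1000 + s)$interval_ms
    approximate_entropy(af) > approximate_entropy(si)
  }, logical(1))
  expect_true(all(wins))
})

test_that("inserted PACs round-trip through the census", {
  rr <- gen_sinus_rr(2 * 3.6e6, 800, 40, seed = 7)
  ins <- insert_pacs(rr, 60, seed = 8)
  expect_gt(nrow(ins$truth), 80)
  pc <- pac_census(ins$beats)
  m <- merge(ins$truth[, c("index", "type")],
             pc$records[, c("index", "type")], by = "index", all.x = TRUE)
  expect_gte(mean(!is.na(m$type.y) & m$type.x == m$type.y), 0.95)

  # zero rate leaves the series untouched
  none <- insert_pacs(rr, 0, seed = 9)
  expect_equal(nrow(none$beats), nrow(rr) + 1)
  expect_null(none$truth)

  # a pure sinus-reset mix contributes nothing countable
  only_reset <- insert_pacs(rr, 30, c(SINUS_RESET = 1, FULL_COMPENSATORY = 0,
                                      INTERPOLATED = 0, DELAYED_RESET = 0),
                            seed = 10)
  expect_equal(pac_census(only_reset$beats)$pac_countable, 0L)
})

test_that("patient generation annotates rhythm segments truthfully", {
  chronic <- gen_patient(rhythm_timeline(
    data.frame(kind = "AF", duration_ms = 2 * 3.6e6)), seed = 11)
  expect_equal(chronic$annotations$kind, "AF")
  expect_equal(nrow(chronic$annotations), 1)

  healthy <- gen_patient(rhythm_timeline(
    data.frame(kind = "SINUS", duration_ms = 2 * 3.6e6)), seed = 12)
  expect_false("AF" %in% healthy$annotations$kind)

  # risk signature: countable-PAC insertions decay after the episode
  tl <- rhythm_timeline(
    data.frame(kind = c("SINUS", "AF", "SINUS"),
               duration_ms = c(1.8e6, 1.8e6, 4 * 3.6e6)),
    risk = TRUE)
  rates <- sapply(1:8, function(s) {
    pat <- gen_patient(tl, seed = 100 + s)
    ep_end <- pat$annotations$end_ms[pat$annotations$kind == "AF"]
    pacs <- pat$pacs$time_ms[pat$pacs$time_ms > ep_end]
    hrs <- (pacs - ep_end) / 3.6e6
    c(sum(hrs < 1), sum(hrs >= 2 & hrs < 3))
  })
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("cohorts are reproducible from the master seed", {
  spec <- cohort_spec(n_paroxysmal = 2, n_chronic = 1, n_healthy = 2,
                      duration_range_h = c(2, 3), seed = 7)
  c1 <- gen_cohort(spec)
  c2 <- gen_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 5)
  expect_identical(lapply(c1$patients, function(p) p$beats$time_ms),
                   lapply(c2$patients, function(p) p$beats$time_ms))
  expect_setequal(unique(c1$manifest$group),
                  c("PAROXYSMAL", "CHRONIC", "HEALTHY"))
  # start times are whole minutes (the study's offsets carry no seconds)
  expect_true(all(c1$manifest$start_clock_s %% 60 == 0))

  empty <- gen_cohort(cohort_spec(0, 0, 0))
  expect_equal(nrow(empty$manifest), 0)
})

test_that("cohort files round-trip through disk", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_paroxysmal = 1, n_chronic = 0, n_healthy = 1,
                      duration_range_h = c(2, 2), seed = 3)
  ch <- gen_cohort(spec, out_dir = dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man), 2)
  b <- read_beats_csv(file.path(dir, man$beats_csv[1]))
  expect_equal(b$time_ms, ch$patients[[man$pseudonym[1]]]$beats$time_ms)
})

test_that("waveform synthesis is deterministic and preserves R-peak times", {
  beats <- rr_beats(gen_sinus_rr(30000, 800, 30, seed = 14))
  r1 <- gen_ecg_waveform(beats, fs = 200, seed = 15)
  r2 <- gen_ecg_waveform(beats, fs = 200, seed = 15)
  expect_identical(r1$leads, r2$leads)
  # each true R time coincides with a local maximum of the clean template
  r_clean <- gen_ecg_waveform(beats, fs = 500, snr_db = 60, n_leads = 1,
                              seed = 16)
  x <- r_clean$leads[[1]]
  for (t in beats$time_ms[2:10]) {
    i <- round(t / 1000 * 500) + 1
    win <- x[(i - 5):(i + 5)]
    expect_lte(abs(which.max(win) - 6), 1)  # within one sample at 500 Hz
  }
})
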