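# A small model trained once per test run; hour-long training snips live in
# the packaged default model, this one uses 30-minute snips to keep the
# suite fast (the feature distributions the classes differ in are
# duration-independent).
local_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      ts <- make_training_set(n_per_class = 50, seed = 101, snip_minutes = 30)
      m <<- train_risk_model(ts$features, ts$labels, seed = 101)
    }
    m
  }
})

test_that("analyzability gate fires on low NN counts, noise, and ectopy load", {
  clean <- feature_vector(healthy_snip_beats(3.6e6, seed = 21))
  expect_length(analyzability_check(clean), 0)
  expect_gt(clean$nn_count, 4000)

  frag <- feature_vector(rr_beats(gen_sinus_rr(1.2e6, 1000, 30, seed = 22)))
  expect_true("NN_TOO_LOW" %in% analyzability_check(frag))  # ~1200 NN

  noisy <- feature_vector(mark_artifacts(healthy_snip_beats(3.6e6, seed = 23),
                                         0.3, seed = 24))
  expect_true("BAD_SIGNAL" %in% analyzability_check(noisy))

  vpc <- insert_vpcs(gen_sinus_rr(3.6e6, 800, 40, seed = 25), 60, seed = 26)
  expect_true("PATHOLOGICAL_QRS" %in%
                analyzability_check(feature_vector(vpc$beats)))
})

test_that("manifest AF is detected with high irregularity and entropy", {
  model <- local_model()
  af <- feature_vector(af_snip_beats(3.6e6, seed = 31))
  expect_true(detect_manifest_af(af, model))
  sinus <- feature_vector(healthy_snip_beats(3.6e6, seed = 32))
  expect_false(detect_manifest_af(sinus, model))

  # regular bigeminy: large RR-difference dispersion but near-zero entropy
  bige <- feature_vector(rr_beats(rr_from_intervals(rep(c(600, 1000), 2400))))
  expect_gt(bige$dnorm_sd, 0.1)
  expect_lt(bige$apen, 0.2)
  expect_false(detect_manifest_af(bige, model))

  # rule mode agrees on the clear cases
  rule_cfg <- sra_config(af_mode = "rule")
  expect_true(detect_manifest_af(af, cfg = rule_cfg))
  expect_false(detect_manifest_af(sinus, cfg = rule_cfg))
  expect_false(detect_manifest_af(bige, cfg = rule_cfg))

  missing <- feature_vector(rr_beats(gen_sinus_rr(30000, 800, 30, seed = 33)))
  expect_error(detect_manifest_af(missing, model), "not analyzable")
})

test_that("snip classification respects category precedence", {
  model <- local_model()
  af_gated <- feature_vector(mark_artifacts(af_snip_beats(3.6e6, seed = 41),
                                            0.35, seed = 42))
  out <- classify_snip(af_gated, model)
  expect_equal(out$category, "NOT_ANALYZABLE")
  expect_true(length(out$reasons) > 0)

  af <- classify_snip(feature_vector(af_snip_beats(3.6e6, seed = 43)), model)
  expect_equal(af$category, "AF")
  expect_length(af$reasons, 0)

  expect_error(classify_snip(feature_vector(healthy_snip_beats(3.6e6, seed = 44)),
                             model = NULL), "model")
})

test_that("risk snips and healthy snips separate at the required rates", {
  model <- local_model()
  n <- 40
  risk_cat <- vapply(seq_len(n), function(i) {
    classify_snip(feature_vector(risk_snip_beats(3.6e6, seed = 200 + 7 * i)),
                  model)$category
  }, character(1))
  healthy_cat <- vapply(seq_len(n), function(i) {
    classify_snip(feature_vector(healthy_snip_beats(3.6e6, seed = 600 + 7 * i)),
                  model)$category
  }, character(1))
  expect_gte(mean(risk_cat == "PAF_RISK"), 0.8)
  expect_gte(mean(healthy_cat == "NO_RISK"), 0.95)
})

test_that("training is deterministic, order-invariant, and serializable", {
  ts <- make_training_set(n_per_class = 50, seed = 55, snip_minutes = 15)
  m1 <- train_risk_model(ts$features, ts$labels, seed = 55)
  m2 <- train_risk_model(ts$features, ts$labels, seed = 55)
  expect_identical(m1$weights, m2$weights)

  perm <- sample(nrow(ts$features))
  m3 <- train_risk_model(ts$features[perm, ], ts$labels[perm], seed = 55)
  probe <- make_training_set(n_per_class = 50, seed = 56, snip_minutes = 15)$features
  expect_identical(risk_scores(m1, probe), risk_scores(m3, probe))

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m1, path)
  m4 <- load_model(path)
  expect_identical(risk_scores(m1, probe), risk_scores(m4, probe))

  # writing the same model twice gives identical files
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(train_risk_model(ts$features, rep("NO_RISK", nrow(ts$features))),
               "2 classes")
  expect_error(train_risk_model(ts$features[1:60, ],
                                rep(c("NO_RISK", "AF"), 30)), "50 examples")
})

test_that("a model generalizes to held-out generator seeds", {
  model <- local_model()
  heldout <- make_training_set(n_per_class = 20, seed = 777, snip_minutes = 30)
  pred <- classify_features(heldout$features, model)$category
  acc <- vapply(unique(heldout$labels), function(cl)
    mean(pred[heldout$labels == cl] == cl), numeric(1))
  expect_gte(mean(acc), 0.85)
})

test_that("the packaged default model loads and behaves sanely", {
  model <- sra_default_model()
  expect_s3_class(model, "sra_model")
  expect_equal(model$kind, "linear_svm_ovr")
  expect_setequal(model$classes, c("NO_RISK", "PAF_RISK", "AF"))
  af <- feature_vector(af_snip_beats(3.6e6, seed = 91))
  expect_equal(classify_snip(af, model)$category, "AF")
})
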