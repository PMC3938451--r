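# Snip gating and the four-way SRA readout: NOT_ANALYZABLE / NO_RISK /
# PAF_RISK / AF. The risk model is a set of one-vs-rest linear
# support-vector machines over the RR feature set, trained on the synthetic
# generator, serialized to JSON (weights + standardization constants) so a
# reloaded model predicts bit-identically.

SRA_CATEGORIES <- c("NOT_ANALYZABLE", "NO_RISK", "PAF_RISK", "AF")

MODEL_FEATURES <- c("sd1_ms", "sd2_ms", "sd_ratio", "dnorm_sd", "dnorm_p95",
                    "extreme_window_ratio", "pac_rate", "apen")

CORE_FEATURES <- c("sd1_ms", "sd2_ms", "dnorm_sd", "extreme_window_ratio",
                   "apen")

# model design matrix from a feature table; pac_rate is countable PACs per
# hour; the SD1/SD2 ratio is capped (it is +Inf for zero-SD2 rhythms)
.model_matrix <- function(features) {
  f <- as.data.frame(features)
  hours <- f$duration_ms / 3.6e6
  m <- cbind(sd1_ms = f$sd1_ms, sd2_ms = f$sd2_ms,
             sd_ratio = pmin(f$sd_ratio, 10),
             dnorm_sd = f$dnorm_sd, dnorm_p95 = f$dnorm_p95,
             extreme_window_ratio = f$extreme_window_ratio,
             pac_rate = f$pac_countable / pmax(hours, 1e-9),
             apen = f$apen)
  m
}

#' Check snip analyzability
#'
#' Mirrors the gating of the screening readout: a snip is not analyzable
#' when its NN-interval count is too low, its signal too noisy, or its
#' ventricular-beat rate pathological; a missing core feature is also a
#' not-analyzable trigger.
#'
#' @param fv a one-row [feature_vector()].
#' @param cfg an [sra_config()].
#' @return character vector of machine-readable failure reasons (subset of
#'   `NN_TOO_LOW`, `BAD_SIGNAL`, `PATHOLOGICAL_QRS`, `MISSING_FEATURE`);
#'   empty when the snip passes.
#' @export
analyzability_check <- function(fv, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  reasons <- character(0)
  if (fv$nn_count < cfg$gate_min_nn) reasons <- c(reasons, "NN_TOO_LOW")
  if (fv$artifact_fraction > cfg$gate_max_artifact) reasons <- c(reasons, "BAD_SIGNAL")
  hours <- max(fv$duration_ms / 3.6e6, 1e-9)
  if (fv$v_count / hours > cfg$gate_max_v_per_hour)
    reasons <- c(reasons, "PATHOLOGICAL_QRS")
  if (!length(reasons) && anyNA(unlist(fv[CORE_FEATURES])))
    reasons <- c(reasons, "MISSING_FEATURE")
  reasons
}

#' Train the risk model
#'
#' Fits one linear support-vector machine per class (one-vs-rest) on
#' standardized features. Training rows are first put into a canonical order
#' (sorted by label, then by feature values), which makes the fit invariant
#' to the order in which examples are supplied. The result is fully
#' described by per-class weight vectors and intercepts plus the
#' standardization constants, so it serializes to JSON and reloads
#' bit-identically.
#'
#' @param features feature table (one [feature_vector()] row per snip).
#' @param labels vector of class labels among `NO_RISK`, `PAF_RISK`, `AF`;
#'   at least 2 classes with at least 50 examples each.
#' @param seed integer seed recorded in the model (the fit itself is
#'   deterministic).
#' @param cost SVM cost parameter.
#' @return an object of class `sra_model`.
#' @export
train_risk_model <- function(features, labels, seed = 42, cost = 1) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% SRA_CATEGORIES[-1]))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training requires at least 2 classes")
  m <- .model_matrix(features)
  ok <- stats::complete.cases(m)
  m <- m[ok, , drop = FALSE]; labels <- labels[ok]
  cnt <- table(labels)
  if (any(cnt < 50)) stop("training requires at least 50 examples per class")
  # canonical row order -> order-invariant training
  ord <- do.call(order, c(list(labels), lapply(seq_len(ncol(m)), function(j) m[, j])))
  m <- m[ord, , drop = FALSE]; labels <- labels[ord]
  center <- colMeans(m)
  scale <- apply(m, 2, sd); scale[scale == 0] <- 1
  z <- sweep(sweep(m, 2, center), 2, scale, "/")
  weights <- matrix(0, length(classes), ncol(m),
                    dimnames = list(classes, colnames(m)))
  intercept <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    y <- factor(ifelse(labels == cl, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(z, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # orient so that class members score higher
    dv <- z %*% w + b
    if (mean(dv[labels == cl]) < mean(dv[labels != cl])) { w <- -w; b <- -b }
    weights[cl, ] <- w
    intercept[cl] <- b
  }
  structure(list(kind = "linear_svm_ovr", version = "1",
                 seed = as.integer(seed), feature_names = colnames(m),
                 classes = classes, center = center, scale = scale,
                 weights = weights, intercept = intercept),
            class = "sra_model")
}

#' Per-class decision values for snip features
#'
#' @param model an `sra_model`.
#' @param features feature table (one or more rows).
#' @return numeric matrix, one row per snip, one column per model class.
#' @export
risk_scores <- function(model, features) {
  stopifnot(inherits(model, "sra_model"))
  m <- .model_matrix(features)[, model$feature_names, drop = FALSE]
  z <- sweep(sweep(m, 2, model$center), 2, model$scale, "/")
  s <- z %*% t(model$weights)
  sweep(s, 2, model$intercept, "+")
}

#' Detect manifest atrial fibrillation in one snip
#'
#' In `model` mode a snip is AF when the model's AF decision value wins,
#' subject to a regularity guard: approximate entropy must also exceed
#' `cfg$af_apen_min`, so strictly patterned rhythms (e.g. bigeminy, which
#' shows large RR-difference dispersion but near-zero entropy) are never
#' called AF. In `rule` mode (dependency-free fallback, `cfg$af_mode =
#' "rule"`) the dual threshold on `dnorm_sd` and `apen` decides directly.
#'
#' @param fv a one-row [feature_vector()] that passed the analyzability
#'   gate.
#' @param model an `sra_model` (required in `model` mode).
#' @param cfg an [sra_config()].
#' @return logical.
#' @export
detect_manifest_af <- function(fv, model = NULL, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  if (anyNA(unlist(fv[CORE_FEATURES]))) stop("not analyzable")
  guard <- fv$apen > cfg$af_apen_min
  if (cfg$af_mode == "rule" || is.null(model)) {
    return(isTRUE(fv$dnorm_sd > cfg$af_dnorm_sd_min && guard))
  }
  s <- risk_scores(model, fv)
  if (!"AF" %in% colnames(s)) return(FALSE)
  isTRUE(colnames(s)[which.max(s[1, ])] == "AF" && guard)
}

#' Classify one snip into the four-way readout
#'
#' Precedence: a gate failure yields `NOT_ANALYZABLE` regardless of
#' features; otherwise manifest AF wins; otherwise the risk model decides
#' between `PAF_RISK` and `NO_RISK`. Pure function of (features, model,
#' config).
#'
#' @inheritParams detect_manifest_af
#' @return list of class `snip_classification` with `category`, `reasons`
#'   (gate codes, empty unless `NOT_ANALYZABLE`), and `scores` (named
#'   per-class decision values, `NA` in rule mode).
#' @export
classify_snip <- function(fv, model = NULL, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  if (cfg$af_mode != "rule" && is.null(model)) stop("no risk model loaded")
  reasons <- analyzability_check(fv, cfg)
  if (length(reasons)) {
    return(structure(list(category = "NOT_ANALYZABLE", reasons = reasons,
                          scores = NULL), class = "snip_classification"))
  }
  scores <- if (!is.null(model)) drop(risk_scores(model, fv)) else NULL
  if (detect_manifest_af(fv, model, cfg)) {
    return(structure(list(category = "AF", reasons = character(0),
                          scores = scores), class = "snip_classification"))
  }
  if (is.null(scores)) {
    # rule mode: flag risk on elevated countable-PAC rate or dispersion
    hours <- max(fv$duration_ms / 3.6e6, 1e-9)
    cat <- if (fv$pac_countable / hours > 10 ||
               fv$dnorm_sd > 0.6 * cfg$af_dnorm_sd_min) "PAF_RISK" else "NO_RISK"
    return(structure(list(category = cat, reasons = character(0),
                          scores = NULL), class = "snip_classification"))
  }
  cand <- intersect(c("PAF_RISK", "NO_RISK"), names(scores))
  cat <- cand[which.max(scores[cand])]
  structure(list(category = cat, reasons = character(0), scores = scores),
            class = "snip_classification")
}

#' @export
print.snip_classification <- function(x, ...) {
  cat("<snip_classification>", x$category,
      if (length(x$reasons)) paste0("[", paste(x$reasons, collapse = ","), "]"),
      "\n")
  invisible(x)
}

#' Classify a feature table row by row
#'
#' @param features feature table.
#' @param model an `sra_model`.
#' @param cfg an [sra_config()].
#' @return data.frame with `category` and semicolon-joined `reasons`.
#' @export
classify_features <- function(features, model = NULL, cfg = sra_config()) {
  features <- as.data.frame(features)
  out <- lapply(seq_len(nrow(features)), function(i)
    classify_snip(features[i, , drop = FALSE], model, cfg))
  data.frame(category = vapply(out, `[[`, "", "category"),
             reasons = vapply(out, function(o) paste(o$reasons, collapse = ";"), ""),
             stringsAsFactors = FALSE)
}

#' Save / load a risk model as JSON
#'
#' Full-precision serialization; a reloaded model produces bit-identical
#' predictions.
#'
#' @param model an `sra_model`.
#' @param path file path.
#' @return `load_model` returns an `sra_model`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sra_model"))
  obj <- list(kind = model$kind, version = model$version, seed = model$seed,
              feature_names = model$feature_names, classes = model$classes,
              center = as.list(model$center), scale = as.list(model$scale),
              weights = lapply(model$classes, function(cl)
                as.list(model$weights[cl, ])),
              intercept = as.list(model$intercept))
  names(obj$weights) <- model$classes
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- o$feature_names
  W <- do.call(rbind, lapply(o$classes, function(cl)
    unlist(o$weights[[cl]])[fn]))
  dimnames(W) <- list(o$classes, fn)
  structure(list(kind = o$kind, version = o$version, seed = o$seed,
                 feature_names = fn, classes = o$classes,
                 center = unlist(o$center)[fn], scale = unlist(o$scale)[fn],
                 weights = W,
                 intercept = setNames(unlist(o$intercept)[o$classes], o$classes)),
            class = "sra_model")
}

#' The packaged default risk model
#'
#' A versioned fixture model trained on the synthetic generator with seed 42
#' (see `scripts/train-default-model.R` in the source repository for the
#' exact recipe).
#'
#' @return an `sra_model`.
#' @export
sra_default_model <- function() {
  load_model(system.file("extdata", "model-default.json",
                         package = "sraholter", mustWork = TRUE))
}

#' Generate a labeled training set from the synthetic generator
#'
#' One-hour snips in three classes: healthy sinus (`NO_RISK`), sinus with
#' the paroxysmal-AF risk signature fully expressed (`PAF_RISK`), and snips
#' containing AF with burden 0.2-1 (`AF`). Snip-level parameters are jittered
#' across draws so the model sees a range of heart rates and variability.
#'
#' @param n_per_class snips per class.
#' @param seed integer seed.
#' @param snip_minutes snip duration.
#' @param cfg an [sra_config()].
#' @return list with `features` (data.frame) and `labels` (character).
#' @export
make_training_set <- function(n_per_class = 100, seed = 42, snip_minutes = 60,
                              cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  dur <- snip_minutes * 6e4
  feats <- list(); labs <- character(0)
  k <- 0L
  for (cls in c("NO_RISK", "PAF_RISK", "AF")) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      si <- sub_seed(seed, k)
      u <- with_rng(si, runif(6))
      beats <- if (cls == "NO_RISK") {
        rr <- gen_sinus_rr(dur, 700 + 300 * u[1], 25 + 30 * u[2],
                           seed = sub_seed(si, 1))
        ins <- insert_pacs(rr, 4 * u[3], pac_mix_benign, seed = sub_seed(si, 2))
        insert_vpcs(ins$beats, 3 * u[4], seed = sub_seed(si, 3))$beats
      } else if (cls == "PAF_RISK") {
        sdnn <- (25 + 30 * u[2]) * (1.4 + 0.5 * u[5])
        rr <- gen_sinus_rr(dur, 700 + 300 * u[1], sdnn, seed = sub_seed(si, 1))
        ins <- insert_pacs(rr, 20 + 40 * u[3], pac_mix_risk,
                           seed = sub_seed(si, 2))
        insert_vpcs(ins$beats, 5 * u[4], seed = sub_seed(si, 3))$beats
      } else {
        burden <- 0.2 + 0.8 * u[5]
        af_ms <- burden * dur
        rr_af <- gen_af_rr(af_ms, 500 + 200 * u[1], 0.15 + 0.15 * u[3],
                           seed = sub_seed(si, 1))
        if (burden >= 0.999) {
          rr_beats(rr_af)
        } else {
          rr_sin <- gen_sinus_rr(dur - af_ms, 700 + 300 * u[1],
                                 25 + 30 * u[2], seed = sub_seed(si, 2))
          rr_beats(rr_from_intervals(c(rr_sin$interval_ms, rr_af$interval_ms)))
        }
      }
      feats[[k]] <- feature_vector(beats, cfg)
      labs <- c(labs, cls)
    }
  }
  list(features = do.call(rbind, feats), labels = labs)
}
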