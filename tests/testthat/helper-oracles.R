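# Independent oracles and small construction helpers used across tests.

# naive O(N^2) approximate entropy, classic Pincus definition
naive_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x); nw <- n - mm + 1
    counts <- vapply(seq_len(nw), function(i) {
      sum(vapply(seq_len(nw), function(j) {
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(counts / nw))
  }
  phi(m) - phi(m + 1)
}

# closed-form eigenvalues of the population covariance of lagged pairs,
# axes assigned by orientation (minor = closer to the (1,-1) direction)
closed_form_poincare <- function(iv) {
  x <- iv[-length(iv)]; y <- iv[-1]
  n <- length(x)
  a <- sum((x - mean(x))^2) / n
  b <- sum((y - mean(y))^2) / n
  cc <- sum((x - mean(x)) * (y - mean(y))) / n
  disc <- sqrt(((a - b) / 2)^2 + cc^2)
  lam_hi <- (a + b) / 2 + disc
  lam_lo <- (a + b) / 2 - disc
  # eigenvector of lam_hi: (cc, lam_hi - a); closer to (1,1) or (1,-1)?
  v <- if (abs(cc) > 1e-300) c(cc, lam_hi - a) else if (a >= b) c(1, 0) else c(0, 1)
  hi_is_identity_axis <- abs(v[1] + v[2]) >= abs(v[1] - v[2])
  if (hi_is_identity_axis) {
    list(sd1 = sqrt(max(lam_lo, 0)), sd2 = sqrt(max(lam_hi, 0)))
  } else {
    list(sd1 = sqrt(max(lam_hi, 0)), sd2 = sqrt(max(lam_lo, 0)))
  }
}

# exhaustive max-sum window search
exhaustive_ewr <- function(iv, L) {
  if (length(iv) < L) return(NA_real_)
  sums <- vapply(seq_len(length(iv) - L + 1), function(i) sum(iv[i:(i + L - 1)]),
                 numeric(1))
  w <- iv[which.max(sums) + 0:(L - 1)]
  min(w) / max(w)
}

# sinus beats carrying the full paroxysmal-AF risk signature
risk_snip_beats <- function(duration_ms, seed, mean_nn = 800, sdnn = 40) {
  rr <- gen_sinus_rr(duration_ms, mean_nn, sdnn * 1.6, seed = seed)
  insert_pacs(rr, 40, pac_mix_risk, seed = seed + 1)$beats
}

healthy_snip_beats <- function(duration_ms, seed, mean_nn = 800, sdnn = 40) {
  rr <- gen_sinus_rr(duration_ms, mean_nn, sdnn, seed = seed)
  insert_pacs(rr, 2, pac_mix_benign, seed = seed + 1)$beats
}

af_snip_beats <- function(duration_ms, seed, mean_nn = 600, cv = 0.2) {
  rr_beats(gen_af_rr(duration_ms, mean_nn, cv, seed = seed))
}

# minimal patient_result stub for evaluation-logic tests
stub_patient <- function(pseudonym, group, categories, annotations = NULL,
                         first_dur = 3.6e6) {
  n <- length(categories)
  starts <- c(0, first_dur + 3.6e6 * (seq_len(n - 1) - 1))
  durs <- c(first_dur, rep(3.6e6, n - 1))
  snips <- data.frame(pseudonym = pseudonym, snip_index = seq_len(n) - 1L,
                      start_ms = starts, duration_ms = durs,
                      category = categories, reasons = "",
                      af_truth_frac = vapply(seq_len(n), function(i) {
                        if (is.null(annotations)) return(0)
                        af <- annotations[annotations$kind == "AF", , drop = FALSE]
                        if (!nrow(af)) return(0)
                        o <- sum(pmax(0, pmin(af$end_ms, starts[i] + durs[i]) -
                                        pmax(af$start_ms, starts[i])))
                        o / durs[i]
                      }, numeric(1)),
                      stringsAsFactors = FALSE)
  has_af <- !is.null(annotations) && any(annotations$kind == "AF")
  structure(list(pseudonym = pseudonym, group = group, snips = snips,
                 first_hour_class = categories[1],
                 any_hour_flag = any(categories %in% c("PAF_RISK", "AF")),
                 assessable = any(categories != "NOT_ANALYZABLE"),
                 holter_af_overall = has_af,
                 holter_af_first_hour = has_af &&
                   any(annotations$kind == "AF" & annotations$start_ms < first_dur),
                 annotations = annotations),
            class = "patient_result")
}
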