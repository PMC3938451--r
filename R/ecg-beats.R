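# QRS detection and morphology-based beat classification on 1-3 leads.
# Detection is Pan-Tompkins-style: band-pass, squared derivative, moving
# integration, adaptive signal/noise thresholds, refractory period. Lead
# quality is scored by cross-checking two independent single-lead detectors.

.bandpass <- function(x, fs, cfg) {
  hi <- min(cfg$bp_high, 0.45 * fs)
  bf <- signal::butter(2, c(cfg$bp_low, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# local maxima indices of v
.local_max <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# energy detector: integrated squared derivative + adaptive threshold
.detect_energy <- function(x, fs, cfg) {
  y <- .bandpass(x, fs, cfg)
  e <- c(0, diff(y))^2
  w <- max(3L, round(0.12 * fs))
  integ <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  cand <- .local_max(integ)
  if (!length(cand)) return(numeric(0))
  ref <- round(cfg$refractory_ms / 1000 * fs)
  init <- integ[seq_len(min(length(integ), 2 * fs))]
  spk <- max(init); npk <- mean(init)
  if (spk <= 0) return(numeric(0))
  last <- -Inf
  keep <- numeric(0)
  for (i in cand) {
    thr <- npk + 0.2 * (spk - npk)
    if (integ[i] > thr && (i - last) >= ref) {
      keep <- c(keep, i)
      last <- i
      spk <- 0.125 * integ[i] + 0.875 * spk
    } else if (integ[i] > thr && (i - last) < ref) {
      # within refractory: keep the larger of the two
      if (integ[i] > integ[last]) { keep[length(keep)] <- i; last <- i }
    } else {
      npk <- 0.125 * integ[i] + 0.875 * npk
    }
  }
  # refine to the bandpassed extremum near each integrated peak
  half <- round(0.1 * fs)
  r <- vapply(keep, function(i) {
    a <- max(1L, i - half); b <- min(length(y), i + half)
    a + which.max(abs(y[a:b])) - 1L
  }, numeric(1))
  sort(unique((r - 1) / fs * 1000))
}

# amplitude detector: bandpassed absolute peaks over a global threshold
.detect_amplitude <- function(x, fs, cfg) {
  y <- abs(.bandpass(x, fs, cfg))
  thr <- 0.45 * as.numeric(quantile(y, 0.995))
  if (thr <= 0) return(numeric(0))
  cand <- .local_max(y)
  cand <- cand[y[cand] > thr]
  if (!length(cand)) return(numeric(0))
  ref <- round(cfg$refractory_ms / 1000 * fs)
  keep <- integer(0); last <- -Inf
  for (i in cand) {
    if ((i - last) >= ref) { keep <- c(keep, i); last <- i }
    else if (y[i] > y[last]) { keep[length(keep)] <- i; last <- i }
  }
  (keep - 1) / fs * 1000
}

# per-10s-window agreement fraction between two detection time vectors (ms);
# windows whose detection count is physiologically implausible (noise fires
# both detectors at the refractory-limited rate) score zero
.window_agreement <- function(t1, t2, duration_ms, cfg) {
  wms <- cfg$quality_window_s * 1000
  nw <- max(1L, floor(duration_ms / wms))
  max_rate <- 3.5 * cfg$quality_window_s / 10  # 210 bpm
  min_rate <- 0.3 * cfg$quality_window_s      # 18 bpm
  vapply(seq_len(nw), function(k) {
    hi <- if (k == nw) duration_ms + 1 else k * wms  # tail joins last window
    a <- t1[t1 >= (k - 1) * wms & t1 < hi]
    b <- t2[t2 >= (k - 1) * wms & t2 < hi]
    if (!length(a) || !length(b)) return(0)
    if (max(length(a), length(b)) > max_rate * 10 ||
        min(length(a), length(b)) < min_rate) return(0)
    m <- sum(vapply(a, function(t) any(abs(b - t) <= cfg$quality_agree_ms),
                    logical(1)))
    m / max(length(a), length(b))
  }, numeric(1))
}

#' Select the best leads of a multi-lead record
#'
#' Scores each lead by the agreement rate between two independent
#' single-lead QRS detectors (an integrated-energy detector and an
#' amplitude-threshold detector): the fraction of matched detections per
#' 10-second window, averaged over the record. A noise lead scores near
#' zero. Ties are broken by lead index, so the selection is deterministic
#' and permutation-equivariant.
#'
#' @param record an [ecg_record()].
#' @param n number of leads to select (at most the number of leads).
#' @param cfg an [sra_config()].
#' @return integer vector of `n` lead indices, best first.
#' @export
select_best_leads <- function(record, n = 2, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  if (!inherits(record, "ecg_record")) stop("no signal")
  n_leads <- length(record$leads)
  if (n > n_leads) stop("n exceeds the number of leads")
  dur <- ecg_duration_ms(record)
  scores <- vapply(seq_len(n_leads), function(l) {
    x <- record$leads[[l]]
    mean(.window_agreement(.detect_energy(x, record$sampling_rate, cfg),
                           .detect_amplitude(x, record$sampling_rate, cfg),
                           dur, cfg))
  }, numeric(1))
  order(-scores, seq_len(n_leads))[seq_len(n)]
}

# saturation / flat-signal windows on a lead; returns logical per window
.bad_windows <- function(x, fs, duration_ms, cfg) {
  wn <- round(cfg$quality_window_s * fs)
  nw <- max(1L, floor(duration_ms / (cfg$quality_window_s * 1000)))
  vapply(seq_len(nw), function(k) {
    seg <- x[((k - 1) * wn + 1):if (k == nw) length(x) else min(length(x), k * wn)]
    sat <- mean(abs(seg) >= cfg$sat_mv)
    flat <- sd(seg) < 1e-6
    sat > 0.05 || flat
  }, logical(1))
}

#' Detect QRS complexes on the best leads of an ECG record
#'
#' Runs the energy detector on each selected lead and fuses the detections:
#' a beat is kept when seen on either lead, detections within the merge
#' window are collapsed, and the refractory period is enforced on the fused
#' train. Saturated or flat 10-second windows are marked artifact: beats
#' inside them are labeled `X` and the record's clean-signal fraction is
#' reduced accordingly. Per-beat morphology (width, amplitude, correlation
#' with the median normal-beat template) is measured on the primary lead.
#'
#' @param record an [ecg_record()] of at least 10 s.
#' @param leads lead indices to use; default the best two (or one for a
#'   single-lead record) per [select_best_leads()].
#' @param cfg an [sra_config()].
#' @return a [beat_series()]; empty with `quality_fraction` 0 for flat or
#'   all-noise input.
#' @export
detect_qrs <- function(record, leads = NULL, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  if (!inherits(record, "ecg_record")) stop("no signal")
  fs <- record$sampling_rate
  dur <- ecg_duration_ms(record)
  if (dur < 10000) stop("record shorter than 10 s")
  if (is.null(leads)) leads <- select_best_leads(record, min(2L, length(record$leads)), cfg)
  det <- lapply(leads, function(l) .detect_energy(record$leads[[l]], fs, cfg))
  pool <- sort(unlist(det))
  empty <- beat_series(numeric(0), character(0),
                       record_id = record$metadata$record_id %||% "rec",
                       quality_fraction = 0, duration_ms = dur)
  if (!length(pool)) return(empty)
  # cluster pooled detections within the merge window
  fused <- numeric(0); cur <- pool[1]; members <- pool[1]
  for (t in pool[-1]) {
    if (t - cur <= cfg$merge_ms) {
      members <- c(members, t)
    } else {
      fused <- c(fused, median(members))
      members <- t
    }
    cur <- t
  }
  fused <- c(fused, median(members))
  # refractory on the fused train
  keep <- fused[1]
  for (t in fused[-1]) if (t - keep[length(keep)] >= cfg$refractory_ms) keep <- c(keep, t)
  # artifact windows from the selected leads
  bad <- Reduce(`|`, lapply(leads, function(l)
    .bad_windows(record$leads[[l]], fs, dur, cfg)))
  wms <- cfg$quality_window_s * 1000
  in_bad <- bad[pmin(length(bad), floor(keep / wms) + 1L)]
  # cross-detector quality on the primary lead
  agree <- .window_agreement(det[[1]],
                             .detect_amplitude(record$leads[[leads[1]]], fs, cfg),
                             dur, cfg)
  good_w <- !bad & agree >= 0.5
  quality <- mean(good_w)
  if (quality == 0 && all(in_bad)) return(empty)
  morph <- .beat_morphology(record$leads[[leads[1]]], fs, keep, cfg)
  beat_series(keep, ifelse(in_bad, "X", "N"),
              width_ms = morph$width_ms, amplitude_mv = morph$amplitude_mv,
              shape_corr = morph$shape_corr,
              record_id = record$metadata$record_id %||% "rec",
              quality_fraction = quality, duration_ms = dur)
}

# morphology in a fixed window around each R peak on the raw signal;
# template = pointwise median over beats with a complete window
.beat_morphology <- function(x, fs, times_ms, cfg) {
  pre <- round(0.15 * fs); post <- round(0.30 * fs)
  n <- length(x)
  idx <- round(times_ms / 1000 * fs) + 1L
  mat <- matrix(NA_real_, nrow = length(idx), ncol = pre + post + 1L)
  for (k in seq_along(idx)) {
    a <- idx[k] - pre; b <- idx[k] + post
    if (a < 1L || b > n) next
    seg <- x[a:b]
    mat[k, ] <- seg - median(seg)
  }
  complete <- which(stats::complete.cases(mat))
  tmpl <- if (length(complete) >= 3L) apply(mat[complete, , drop = FALSE], 2, median) else NULL
  width <- amp <- corr <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    v <- mat[k, ]
    if (anyNA(v)) next
    pk <- which.max(abs(v[(pre - round(0.05 * fs)):(pre + round(0.05 * fs))])) +
      pre - round(0.05 * fs) - 1L
    amp[k] <- abs(v[pk])
    above <- abs(v) > 0.25 * amp[k]
    # contiguous run containing the peak
    lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- pk; while (hi < length(v) && above[hi + 1L]) hi <- hi + 1L
    width[k] <- (hi - lo + 1L) / fs * 1000
    if (!is.null(tmpl) && sd(v) > 0 && sd(tmpl) > 0) corr[k] <- cor(v, tmpl)
  }
  list(width_ms = width, amplitude_mv = amp, shape_corr = corr)
}

#' Classify beats as normal or ventricular from morphology
#'
#' Beats wider than the widened-QRS threshold or correlating poorly with the
#' normal-beat template are labeled `V`; the rest keep a provisional `N`.
#' Artifact (`X`) and atrial (`A`) labels are preserved. With fewer than
#' `min_template_beats` usable beats no template can be formed and every
#' beat is labeled `X` (reason `"too few beats for template"` attached as
#' attribute `reason`).
#'
#' @param beats a [beat_series()] with morphology columns.
#' @param cfg an [sra_config()].
#' @return a `beat_series` with updated labels.
#' @export
classify_beats <- function(beats, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  usable <- beats$label != "X"
  if (sum(usable) < cfg$min_template_beats) {
    beats$label <- rep("X", nrow(beats))
    attr(beats, "reason") <- "too few beats for template"
    return(beats)
  }
  sel <- beats$label %in% c("N", "V")
  wide <- !is.na(beats$width_ms) & beats$width_ms > cfg$wide_qrs_ms
  dissim <- !is.na(beats$shape_corr) & beats$shape_corr < cfg$shape_corr_min
  beats$label[sel] <- ifelse((wide | dissim)[sel], "V", "N")
  beats
}
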