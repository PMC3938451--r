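#' Poincare plot descriptors SD1, SD2 and their ratio
#'
#' Principal-component analysis of the lagged scatter (Ri, Ri+1) over pairs
#' of adjacent NN intervals. The population covariance of the point cloud is
#' eigendecomposed; SD1 is the dispersion along the axis closer to the
#' (1, -1) direction (perpendicular to the line of identity, short-term
#' variability) and SD2 along the axis closer to (1, 1) (long-term
#' variability).
#'
#' @param rr an [build_rr()] series.
#' @param cfg an [sra_config()].
#' @return list with `sd1_ms`, `sd2_ms`, `sd_ratio` (`Inf` when SD2 = 0;
#'   all `NA` when fewer than `cfg$min_nn_poincare` usable pairs).
#' @export
poincare_descriptors <- function(rr, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  p <- nn_adjacent_pairs(rr)
  if (nrow(p) < cfg$min_nn_poincare) {
    return(list(sd1_ms = NA_real_, sd2_ms = NA_real_, sd_ratio = NA_real_))
  }
  x <- p$x; y <- p$y
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  # population (1/N) covariance
  a <- sum((x - mx)^2) / n
  b <- sum((y - my)^2) / n
  cc <- sum((x - mx) * (y - my)) / n
  e <- eigen(matrix(c(a, cc, cc, b), 2, 2), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  # axis orientation: |dot with (1,-1)| largest -> SD1 axis
  d1 <- abs(e$vectors[1, ] - e$vectors[2, ])
  i1 <- which.max(d1)
  sd1 <- sqrt(ev[i1])
  sd2 <- sqrt(ev[-i1][1])
  list(sd1_ms = sd1, sd2_ms = sd2,
       sd_ratio = if (sd2 == 0) Inf else sd1 / sd2)
}

# pairs (Ri, Ri+1) where both intervals are NN and adjacent
nn_adjacent_pairs <- function(rr) {
  n <- nrow(rr)
  if (n < 2L) return(data.frame(x = numeric(0), y = numeric(0)))
  ok <- rr$is_nn[-n] & rr$is_nn[-1L]
  data.frame(x = rr$interval_ms[-n][ok], y = rr$interval_ms[-1L][ok])
}

#' Normalized RR-difference sequence and summary statistics
#'
#' For each pair of adjacent NN intervals the difference is normalized by
#' the mean of the two intervals: (Ri - Ri+1) / (Ri + Ri+1). Values are
#' bounded in (-1, 1) for any positive series.
#'
#' @inheritParams poincare_descriptors
#' @return list with `values`, and summaries `dnorm_mean`, `dnorm_sd`
#'   (sample SD), `dnorm_p95` (95th percentile of absolute values).
#' @export
normalized_rr_differences <- function(rr, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  p <- nn_adjacent_pairs(rr)
  if (nrow(p) < cfg$min_nn_dnorm) {
    return(list(values = numeric(0), dnorm_mean = NA_real_,
                dnorm_sd = NA_real_, dnorm_p95 = NA_real_))
  }
  d <- (p$x - p$y) / (p$x + p$y)
  list(values = d, dnorm_mean = mean(d), dnorm_sd = sd(d),
       dnorm_p95 = as.numeric(quantile(abs(d), 0.95, names = FALSE)))
}

#' Extreme-window ratio
#'
#' Locates, among contiguous runs of NN intervals, the window of
#' `window_len` consecutive intervals with the largest sum (ties broken by
#' earliest position) and returns the ratio of the shortest to the longest
#' interval inside that window.
#'
#' @inheritParams poincare_descriptors
#' @param window_len window length in intervals (default from `cfg`).
#' @return ratio in (0, 1], or `NA` when no NN run is long enough.
#' @export
extreme_window_ratio <- function(rr, window_len = NULL, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  L <- if (is.null(window_len)) cfg$window_len else window_len
  stopifnot(L >= 2)
  best_sum <- -Inf; best <- NULL
  r <- rle(rr$is_nn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < L) next
    v <- rr$interval_ms[starts[k]:ends[k]]
    cs <- c(0, cumsum(v))
    sums <- cs[(L + 1):length(cs)] - cs[1:(length(cs) - L)]
    j <- which.max(sums)  # earliest maximum within the run
    if (sums[j] > best_sum) {
      best_sum <- sums[j]
      best <- v[j:(j + L - 1)]
    }
  }
  if (is.null(best)) return(NA_real_)
  min(best) / max(best)
}

#' Approximate entropy of an RR series
#'
#' Classic regularity statistic ApEn(m, r): Chebyshev distance,
#' self-matches included, tolerance `r` expressed as a multiple of the
#' series standard deviation. Computed over the NN intervals when given an
#' `rr_series`, or over the vector as-is when given a numeric vector.
#'
#' @param x an `rr_series` or a numeric vector.
#' @param cfg an [sra_config()] supplying `apen_m`, `apen_r_factor`, and the
#'   `min_nn_apen` precondition (applied to `rr_series` input only).
#' @return non-negative ApEn value; 0 for a zero-variance series; `NA` when
#'   the series is too short.
#' @export
approximate_entropy <- function(x, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  if (inherits(x, "rr_series")) {
    v <- x$interval_ms[x$is_nn]
    if (length(v) < cfg$min_nn_apen) return(NA_real_)
  } else {
    v <- as.numeric(x)
  }
  if (length(v) < cfg$apen_m + 2) return(NA_real_)
  s <- sd(v)
  if (s == 0) return(0)
  .apen_cpp(v, as.integer(cfg$apen_m), cfg$apen_r_factor * s)
}

#' Premature-atrial-complex census and typing
#'
#' Scans a beat series for premature narrow-QRS beats and types each one by
#' its coupling interval CI and post-extrasystolic pause P relative to the
#' local sinus cycle length NN (median of the `local_nn_k` nearest NN
#' intervals):
#' \itemize{
#'   \item `INTERPOLATED`: CI + P within `pac_tol` of NN;
#'   \item `FULL_COMPENSATORY`: CI + P within `pac_tol` of 2 NN;
#'   \item `DELAYED_RESET`: P > `delayed_pause_factor` x NN and
#'     CI + P < (1 - `pac_tol`) x 2 NN;
#'   \item `SINUS_RESET` otherwise (pause about one sinus cycle).
#' }
#' A beat is premature when CI < `prematurity_factor` x NN. Only beats with
#' normal neighbours and narrow QRS are considered; only types other than
#' `SINUS_RESET` are countable (those are the complexes fed to the risk
#' classifier).
#'
#' @param beats a [beat_series()].
#' @param cfg an [sra_config()].
#' @return list with `records` (data.frame: `index`, `time_ms`,
#'   `coupling_ms`, `pause_ms`, `local_nn_ms`, `type`, `countable`),
#'   `pac_total`, `pac_countable`.
#' @export
pac_census <- function(beats, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  empty <- data.frame(index = integer(0), time_ms = numeric(0),
                      coupling_ms = numeric(0), pause_ms = numeric(0),
                      local_nn_ms = numeric(0), type = character(0),
                      countable = logical(0), stringsAsFactors = FALSE)
  n <- nrow(beats)
  if (n < 3L) return(list(records = empty, pac_total = 0L, pac_countable = 0L))
  iv <- diff(beats$time_ms)
  lab <- beats$label
  nn_iv <- lab[-n] == "N" & lab[-1L] == "N"
  nn_idx <- which(nn_iv)
  if (length(nn_idx) < cfg$local_nn_k + 2L)
    return(list(records = empty, pac_total = 0L, pac_countable = 0L))
  # cheap prefilter: only beats whose coupling interval is short against a
  # running median can possibly be premature under the exact local-NN rule
  rm_k <- min(21L, 2L * (length(iv) %/% 2L) - 1L)
  roll <- if (length(iv) >= rm_k && rm_k >= 3L)
    stats::runmed(iv, rm_k, endrule = "median") else rep(median(iv), length(iv))
  cand_k <- which(iv[-length(iv)] < cfg$prematurity_factor * 1.25 *
                    roll[-length(iv)]) + 1L
  cand_k <- cand_k[cand_k >= 2L & cand_k <= n - 1L]
  recs <- list()
  flagged <- logical(n)
  for (k in cand_k) {
    if (!(lab[k] %in% c("N", "A"))) next
    if (flagged[k - 1L]) next  # interval before k is a PAC's pause, not a CI
    if (!is.na(beats$width_ms[k]) && beats$width_ms[k] > cfg$wide_qrs_ms) next
    if (lab[k - 1L] != "N" || lab[k + 1L] != "N") next
    ci <- iv[k - 1L]; pp <- iv[k]
    # nearest local_nn_k NN intervals by index, excluding the CI and pause:
    # a +/-12 slice of the sorted NN index list covers them
    pos <- findInterval(k, nn_idx)
    sl <- nn_idx[max(1L, pos - 12L):min(length(nn_idx), pos + 12L)]
    sl <- sl[sl != k - 1L & sl != k]
    if (length(sl) < cfg$local_nn_k) next
    sl <- sl[order(abs(sl - k))][seq_len(cfg$local_nn_k)]
    nn <- median(iv[sl])
    if (ci >= cfg$prematurity_factor * nn) next
    s <- ci + pp
    type <- if (abs(s - nn) < cfg$pac_tol * nn) {
      "INTERPOLATED"
    } else if (abs(s - 2 * nn) < cfg$pac_tol * 2 * nn) {
      "FULL_COMPENSATORY"
    } else if (pp > cfg$delayed_pause_factor * nn &&
               s < (1 - cfg$pac_tol) * 2 * nn) {
      "DELAYED_RESET"
    } else {
      "SINUS_RESET"
    }
    flagged[k] <- TRUE
    recs[[length(recs) + 1L]] <- data.frame(
      index = k, time_ms = beats$time_ms[k], coupling_ms = ci, pause_ms = pp,
      local_nn_ms = nn, type = type, countable = type != "SINUS_RESET",
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty
  list(records = records, pac_total = nrow(records),
       pac_countable = sum(records$countable))
}

#' Assemble the full snip feature vector
#'
#' Runs every RR feature on one snip of beats. Features whose precondition
#' is not met are carried as `NA` (explicit missing markers), never silent
#' zeros; the downstream analyzability gate treats a missing core feature as
#' a not-analyzable trigger.
#'
#' @param beats a [beat_series()] for one snip (nominally at most 1 hour).
#' @param cfg an [sra_config()].
#' @return one-row `data.frame` of class `sra_features` with columns
#'   `sd1_ms`, `sd2_ms`, `sd_ratio`, `dnorm_mean`, `dnorm_sd`, `dnorm_p95`,
#'   `extreme_window_ratio`, `pac_countable`, `pac_total`, `apen`,
#'   `nn_count`, `artifact_fraction`, `v_count`, `duration_ms`.
#' @export
feature_vector <- function(beats, cfg = sra_config()) {
  cfg <- as_sra_config(cfg)
  dur <- beats_duration_ms(beats)
  art <- if (nrow(beats)) {
    max(1 - beats_quality(beats), mean(beats$label == "X"))
  } else 1
  v_count <- sum(beats$label == "V")
  if (nrow(beats) < 2L) {
    fv <- data.frame(sd1_ms = NA_real_, sd2_ms = NA_real_, sd_ratio = NA_real_,
                     dnorm_mean = NA_real_, dnorm_sd = NA_real_,
                     dnorm_p95 = NA_real_, extreme_window_ratio = NA_real_,
                     pac_countable = 0L, pac_total = 0L, apen = NA_real_,
                     nn_count = 0L, artifact_fraction = art,
                     v_count = v_count, duration_ms = dur)
    class(fv) <- c("sra_features", "data.frame")
    return(fv)
  }
  rr <- build_rr(beats)
  pc <- poincare_descriptors(rr, cfg)
  dn <- normalized_rr_differences(rr, cfg)
  pac <- pac_census(beats, cfg)
  fv <- data.frame(
    sd1_ms = pc$sd1_ms, sd2_ms = pc$sd2_ms, sd_ratio = pc$sd_ratio,
    dnorm_mean = dn$dnorm_mean, dnorm_sd = dn$dnorm_sd,
    dnorm_p95 = dn$dnorm_p95,
    extreme_window_ratio = extreme_window_ratio(rr, cfg = cfg),
    pac_countable = pac$pac_countable, pac_total = pac$pac_total,
    apen = approximate_entropy(rr, cfg),
    nn_count = sum(rr$is_nn), artifact_fraction = art,
    v_count = v_count, duration_ms = dur)
  class(fv) <- c("sra_features", "data.frame")
  fv
}

#' Read / write snip feature tables as CSV
#'
#' One row per snip; columns exactly the [feature_vector()] fields (plus any
#' identifier columns already present).
#'
#' @param features data.frame of feature rows.
#' @param path file path.
#' @return `read_features_csv` returns a data.frame; `write_features_csv`
#'   returns `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
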