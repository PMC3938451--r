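#' ECG record container
#'
#' Holds 1-3 equal-length sampled leads (mV), the sampling rate, the clock
#' time at which recording started, and free-form metadata.
#'
#' @param leads list of numeric vectors, one per lead, all the same length.
#' @param sampling_rate samples per second (Hz), > 0.
#' @param start_time recording start as seconds since midnight (may exceed
#'   86400 to carry a day ordinal).
#' @param metadata named list; may contain identifiers (see
#'   [pseudonymize()]).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(leads, sampling_rate, start_time = 0, metadata = list()) {
  if (!is.list(leads) || length(leads) < 1L) stop("no signal")
  lens <- vapply(leads, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all leads must have equal length")
  if (lens[1] == 0L) stop("no signal")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(list(leads = lapply(leads, as.numeric),
                 sampling_rate = sampling_rate,
                 start_time = start_time,
                 metadata = metadata),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d lead(s), %.1f s @ %g Hz\n",
              length(x$leads), length(x$leads[[1]]) / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

ecg_duration_ms <- function(record) {
  1000 * length(record$leads[[1]]) / record$sampling_rate
}

#' Beat series container
#'
#' A time-ordered table of detected beats. Labels: `N` normal, `V`
#' ventricular, `A` atrial-premature, `X` artifact/unclassifiable.
#'
#' @param time_ms beat (R-peak) times from record start, strictly increasing.
#' @param label character vector in `c("N","V","A","X")`.
#' @param width_ms,amplitude_mv,shape_corr per-beat morphology metrics
#'   (`shape_corr` is the correlation against the running normal-beat
#'   template, in `[-1, 1]`); `NA` when unknown.
#' @param record_id identifier carried through to outputs.
#' @param quality_fraction fraction of the record judged clean signal,
#'   in `[0, 1]`.
#' @param duration_ms total record duration; defaults to the last beat time.
#' @return a `data.frame` of class `beat_series` with attributes
#'   `record_id`, `quality_fraction`, `duration_ms`.
#' @export
beat_series <- function(time_ms, label = rep("N", length(time_ms)),
                        width_ms = NA_real_, amplitude_mv = NA_real_,
                        shape_corr = NA_real_, record_id = "rec",
                        quality_fraction = 1, duration_ms = NULL) {
  n <- length(time_ms)
  if (n > 1L && any(diff(time_ms) <= 0)) stop("beat times must be strictly increasing")
  if (!all(label %in% c("N", "V", "A", "X"))) stop("invalid beat label")
  if (quality_fraction < 0 || quality_fraction > 1) stop("quality_fraction must be in [0,1]")
  df <- data.frame(time_ms = as.numeric(time_ms),
                   label = rep_len(as.character(label), n),
                   width_ms = rep_len(as.numeric(width_ms), n),
                   amplitude_mv = rep_len(as.numeric(amplitude_mv), n),
                   shape_corr = rep_len(as.numeric(shape_corr), n),
                   stringsAsFactors = FALSE)
  structure(df,
            class = c("beat_series", "data.frame"),
            record_id = record_id,
            quality_fraction = quality_fraction,
            duration_ms = if (is.null(duration_ms)) {
              if (n) max(time_ms) else 0
            } else duration_ms)
}

beats_duration_ms <- function(beats) {
  d <- attr(beats, "duration_ms")
  if (is.null(d)) d <- if (nrow(beats)) max(beats$time_ms) else 0
  d
}

beats_quality <- function(beats) {
  q <- attr(beats, "quality_fraction")
  if (is.null(q)) 1 else q
}

#' Read and write beat tables as CSV
#'
#' Column schema: `time_ms,label,width_ms,amplitude_mv,shape_corr`.
#'
#' @param beats a [beat_series()].
#' @param path file path.
#' @param record_id,quality_fraction,duration_ms attributes to attach on
#'   read (the CSV itself carries only per-beat columns).
#' @return `read_beats_csv` returns a `beat_series`; `write_beats_csv`
#'   returns `path` invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  write.csv(as.data.frame(beats)[, c("time_ms", "label", "width_ms",
                                     "amplitude_mv", "shape_corr")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path, record_id = "rec", quality_fraction = 1,
                           duration_ms = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  beat_series(df$time_ms, df$label, df$width_ms, df$amplitude_mv,
              df$shape_corr, record_id = record_id,
              quality_fraction = quality_fraction, duration_ms = duration_ms)
}

#' Read a multi-lead ECG from CSV
#'
#' One column per lead, header `lead1..leadN`; the sampling rate is supplied
#' by the caller (CSV carries samples only).
#'
#' @param path file path.
#' @param sampling_rate Hz.
#' @param start_time clock start, seconds since midnight.
#' @return an [ecg_record()].
#' @export
read_ecg_csv <- function(path, sampling_rate, start_time = 0) {
  df <- read.csv(path)
  ecg_record(as.list(df), sampling_rate, start_time = start_time)
}

#' RR-interval series
#'
#' Consecutive inter-beat intervals derived from a [beat_series()]. An
#' interval is an NN interval only when both bounding beats are labeled `N`.
#'
#' @param beats a `beat_series` with at least two beats.
#' @return a `data.frame` of class `rr_series` with columns `interval_ms`,
#'   `is_nn`, `label_prev`, `label_next` and attribute `time_ms` (onset time
#'   of each interval).
#' @export
build_rr <- function(beats) {
  if (nrow(beats) < 2L) stop("no intervals")
  iv <- diff(beats$time_ms)
  lp <- beats$label[-nrow(beats)]
  ln <- beats$label[-1L]
  structure(data.frame(interval_ms = iv,
                       is_nn = lp == "N" & ln == "N",
                       label_prev = lp, label_next = ln,
                       stringsAsFactors = FALSE),
            class = c("rr_series", "data.frame"),
            time_ms = beats$time_ms[-nrow(beats)])
}

#' Wrap a bare interval vector as an RR series
#'
#' All bounding beats are taken as normal (`N`).
#'
#' @param intervals_ms positive interval durations.
#' @param start_ms time of the first beat.
#' @return an `rr_series`.
#' @export
rr_from_intervals <- function(intervals_ms, start_ms = 0) {
  stopifnot(all(intervals_ms > 0))
  t <- start_ms + cumsum(c(0, intervals_ms))
  build_rr(beat_series(t))
}

#' Materialize the beat series underlying an RR series
#'
#' @param rr an `rr_series`.
#' @param record_id identifier for the resulting series.
#' @param labels optional per-beat labels; defaults to the labels implied by
#'   the series itself.
#' @return a [beat_series()] with nominal narrow-QRS morphology.
#' @export
rr_beats <- function(rr, record_id = "rec", labels = NULL) {
  t0 <- attr(rr, "time_ms")[1]
  t <- c(attr(rr, "time_ms"), attr(rr, "time_ms")[nrow(rr)] + rr$interval_ms[nrow(rr)])
  if (is.null(labels)) labels <- c(rr$label_prev, rr$label_next[nrow(rr)])
  beat_series(t, labels, width_ms = 90, amplitude_mv = 1, shape_corr = 1,
              record_id = record_id)
}
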