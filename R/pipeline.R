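# Clock-aligned hour-snip segmentation (Holter "first hour" convention),
# pseudonymization, and the per-patient pipeline: features + classification
# per snip, aggregated to patient level.

#' Segment a recording into clock-aligned 1-hour snips
#'
#' Snip 0 runs from the start of recording to the next full clock hour
#' (hence is at most 60 minutes, and exactly 60 only when recording starts
#' on the hour); subsequent snips are full clock hours; the trailing
#' incomplete hour is discarded. Snip durations plus the discarded tail sum
#' exactly to the recording duration.
#'
#' @param beats a [beat_series()] for the full recording.
#' @param start_clock_s recording start as seconds since midnight.
#' @param duration_ms recording duration; defaults to the beat-series
#'   duration attribute.
#' @param truncate_offset_to_minutes drop the seconds of `start_clock_s`
#'   before segmenting (compatibility with offset data recorded without
#'   seconds).
#' @return list of class `snip_list`: each element has `index` (0 = first
#'   hour), `start_ms`, `end_ms`, `duration_ms` and `beats` (times kept on
#'   the recording clock); attribute `discarded_ms` carries the tail length.
#' @export
segment_recording <- function(beats, start_clock_s, duration_ms = NULL,
                              truncate_offset_to_minutes = FALSE) {
  if (truncate_offset_to_minutes) start_clock_s <- 60 * (start_clock_s %/% 60)
  dur <- if (is.null(duration_ms)) beats_duration_ms(beats) else duration_ms
  first_ms <- 1000 * ((3600 - start_clock_s %% 3600) %% 3600)
  if (first_ms == 0) first_ms <- 3.6e6
  if (dur < first_ms) {
    warning("recording shorter than the first-hour remainder; single short snip")
    bounds <- c(0, dur)
  } else {
    bounds <- c(0, seq(first_ms, dur, by = 3.6e6))
  }
  snips <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    in_snip <- beats$time_ms >= a & beats$time_ms < b
    sub <- beats[in_snip, , drop = FALSE]
    q <- if (nrow(sub)) 1 - mean(sub$label == "X") else 0
    sb <- beat_series(sub$time_ms, sub$label, sub$width_ms, sub$amplitude_mv,
                      sub$shape_corr, record_id = attr(beats, "record_id"),
                      quality_fraction = q, duration_ms = b - a)
    snips[[i]] <- list(index = i - 1L, start_ms = a, end_ms = b,
                       duration_ms = b - a, beats = sb)
  }
  structure(snips, class = "snip_list",
            discarded_ms = dur - bounds[length(bounds)])
}

# FNV-1a 32-bit over the UTF-8 bytes of a string, arithmetic kept exact in
# doubles by splitting the state into 16-bit halves
.fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(enc2utf8(s)))) {
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)
    h <- hi * 65536 + lo
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

#' Stable pseudonym for a patient identifier
#'
#' Keyed 32-bit FNV-1a hash: the same identifier always maps to the same
#' pseudonym for a given salt, so repeat recordings of one patient share a
#' pseudonym without any identifier surviving in the output.
#'
#' @param id patient identifier string.
#' @param salt integer or string key.
#' @return pseudonym string like `"P1A2B3C4"`.
#' @export
pseudonym_for <- function(id, salt = 0) {
  h <- .fnv1a32(paste0(salt, ":", id))
  sprintf("P%04X%04X", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pseudonymize record metadata
#'
#' Strips every identifying field (initials, birth date, patient numbers,
#' device ids, recording date/time) from a metadata list, keeping only a
#' stable pseudonym, the group label if present, and relative times.
#' Idempotent: already-sanitized metadata passes through unchanged. The
#' id-to-pseudonym mapping is returned separately so it can be stored apart
#' from the sanitized data.
#'
#' @param metadata named list; the identifier is taken from `patient_id`
#'   (or an existing `pseudonym`).
#' @param salt hash key, see [pseudonym_for()].
#' @return list with `metadata` (sanitized) and `mapping` (data.frame
#'   `patient_id`, `pseudonym`; empty when input was already sanitized).
#' @export
pseudonymize <- function(metadata, salt = 0) {
  keep <- intersect(names(metadata), c("group", "relative_start_ms"))
  if (!is.null(metadata$pseudonym) && is.null(metadata$patient_id)) {
    out <- c(list(pseudonym = metadata$pseudonym), metadata[keep])
    return(list(metadata = out,
                mapping = data.frame(patient_id = character(0),
                                     pseudonym = character(0))))
  }
  id <- metadata$patient_id
  if (is.null(id)) stop("metadata carries neither patient_id nor pseudonym")
  ps <- pseudonym_for(id, salt)
  list(metadata = c(list(pseudonym = ps), metadata[keep]),
       mapping = data.frame(patient_id = id, pseudonym = ps,
                            stringsAsFactors = FALSE))
}

# AF-annotation overlap (ms) with a window
.af_overlap_ms <- function(annotations, a, b) {
  if (is.null(annotations)) return(0)
  af <- annotations[annotations$kind == "AF", , drop = FALSE]
  if (!nrow(af)) return(0)
  sum(pmax(0, pmin(af$end_ms, b) - pmax(af$start_ms, a)))
}

#' Run the full snip pipeline on one patient
#'
#' Segments the recording, extracts the feature vector and classifies each
#' snip, and aggregates to patient level. When ground-truth rhythm
#' annotations are supplied (benchmark mode), each snip also carries its
#' true AF-burden fraction and the patient the Holter-style detection
#' booleans (manifest AF anywhere / in the first hour).
#'
#' @param beats a [beat_series()] covering the recording.
#' @param model an `sra_model` (or NULL in rule mode).
#' @param start_clock_s recording start, seconds since midnight.
#' @param pseudonym,group carried into the result.
#' @param annotations optional data.frame `start_ms,end_ms,kind` with
#'   `kind` in `SINUS`/`AF`.
#' @param cfg an [sra_config()].
#' @param ... passed to [segment_recording()].
#' @return list of class `patient_result`: `pseudonym`, `group`, `snips`
#'   (one row per snip: `snip_index`, `start_ms`, `duration_ms`, `category`,
#'   `reasons`, `af_truth_frac`), `first_hour_class`, `any_hour_flag`,
#'   `assessable`, `holter_af_overall`, `holter_af_first_hour`.
#' @export
run_patient <- function(beats, model, start_clock_s, pseudonym = "P0",
                        group = NA_character_, annotations = NULL,
                        cfg = sra_config(), ...) {
  cfg <- as_sra_config(cfg)
  snips <- segment_recording(beats, start_clock_s, ...)
  rows <- lapply(snips, function(s) {
    fv <- feature_vector(s$beats, cfg)
    cl <- classify_snip(fv, model, cfg)
    data.frame(pseudonym = pseudonym, snip_index = s$index,
               start_ms = s$start_ms, duration_ms = s$duration_ms,
               category = cl$category,
               reasons = paste(cl$reasons, collapse = ";"),
               af_truth_frac = .af_overlap_ms(annotations, s$start_ms, s$end_ms) /
                 s$duration_ms,
               stringsAsFactors = FALSE)
  })
  snip_df <- do.call(rbind, rows)
  assessable <- any(snip_df$category != "NOT_ANALYZABLE")
  structure(list(
    pseudonym = pseudonym, group = group, snips = snip_df,
    first_hour_class = snip_df$category[snip_df$snip_index == 0L],
    any_hour_flag = any(snip_df$category %in% c("PAF_RISK", "AF")),
    assessable = assessable,
    holter_af_overall = if (is.null(annotations)) NA else
      .af_overlap_ms(annotations, 0, beats_duration_ms(beats)) > 0,
    holter_af_first_hour = if (is.null(annotations)) NA else
      .af_overlap_ms(annotations, 0, snip_df$duration_ms[1]) > 0,
    annotations = annotations),
    class = "patient_result")
}

#' Run the pipeline over a generated cohort
#'
#' @param cohort output of [gen_cohort()].
#' @param model an `sra_model`.
#' @param cfg an [sra_config()].
#' @return list of `patient_result`, named by pseudonym.
#' @export
run_cohort <- function(cohort, model, cfg = sra_config()) {
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  names(out) <- man$pseudonym
  for (i in seq_len(nrow(man))) {
    ps <- man$pseudonym[i]
    pat <- cohort$patients[[ps]]
    out[[ps]] <- run_patient(pat$beats, model, man$start_clock_s[i],
                             pseudonym = ps, group = man$group[i],
                             annotations = pat$annotations, cfg = cfg)
  }
  out
}

#' Collect per-snip classification rows from patient results
#'
#' @param results list of `patient_result`.
#' @return one data.frame, rows from every patient's snip table.
#' @export
snip_table <- function(results) {
  do.call(rbind, c(lapply(results, `[[`, "snips"), make.row.names = FALSE))
}

#' Patient-level summary table
#'
#' @param results list of `patient_result`.
#' @return data.frame with one row per patient: group, first-hour class,
#'   any-hour flag, assessability, Holter-style AF booleans.
#' @export
patient_summary <- function(results) {
  do.call(rbind, c(lapply(results, function(r) data.frame(
    pseudonym = r$pseudonym, group = r$group,
    first_hour_class = r$first_hour_class, any_hour_flag = r$any_hour_flag,
    assessable = r$assessable, holter_af_overall = r$holter_af_overall,
    holter_af_first_hour = r$holter_af_first_hour,
    stringsAsFactors = FALSE)), make.row.names = FALSE))
}
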