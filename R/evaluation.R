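# Diagnostic-accuracy statistics: 2x2 confusion tables with exact rational
# sensitivity/specificity, patient-level first-hour statistics, post-episode
# sensitivities, Holter detection rates, and replay of the packaged study
# contingency-table fixtures.

#' Construct a 2x2 confusion table
#'
#' @param tp,fn,fp,tn non-negative counts (predicted x truth).
#' @return list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(counts), class = "confusion_table")
}

#' Cross-tabulate binary predictions against truth
#'
#' @param pred,truth logical (or 0/1) vectors of equal length, no missing
#'   entries.
#' @return a [confusion_table()].
#' @export
confusion_from_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (anyNA(pred) || anyNA(truth)) stop("missing entries")
  confusion_table(tp = sum(pred & truth), fn = sum(!pred & truth),
                  fp = sum(pred & !truth), tn = sum(!pred & !truth))
}

#' Sensitivity and specificity of a confusion table
#'
#' Exact rationals (numerators and denominators retained); rounding is a
#' presentation concern only — `print` rounds half-up to `decimals`, the
#' convention of printed clinical tables.
#'
#' @param t a [confusion_table()].
#' @param decimals digits used by the print method.
#' @return list of class `diagnostic_summary` with `sensitivity` and
#'   `specificity`, each a list `value`, `numerator`, `denominator`
#'   (`value` is `NA` on a zero denominator).
#' @export
sensitivity_specificity <- function(t, decimals = 2) {
  stopifnot(inherits(t, "confusion_table"))
  mk <- function(num, den) list(value = if (den > 0) num / den else NA_real_,
                                numerator = num, denominator = den)
  structure(list(sensitivity = mk(t$tp, t$tp + t$fn),
                 specificity = mk(t$tn, t$fp + t$tn),
                 decimals = decimals),
            class = "diagnostic_summary")
}

#' Round half-up at a fixed number of decimals
#'
#' Presentation-layer rounding matching printed clinical tables (base R
#' `round` is round-half-even).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  f <- function(s, lab) {
    if (is.na(s$value))
      cat(sprintf("%s: undefined (0 denominator)\n", lab))
    else
      cat(sprintf("%s %d/%d = %.*f\n", lab, s$numerator, s$denominator,
                  x$decimals, round_half_up(s$value, x$decimals)))
  }
  f(x$sensitivity, "Sensitivity")
  f(x$specificity, "Specificity")
  invisible(x)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Load a packaged study fixture
#'
#' Fixtures transcribe the study's per-patient and per-snip outcome counts
#' (contingency tables and results-text ratios) as CSVs with schema
#' `group,stratum,positive,total`. Available names: `table2`, `table3`,
#' `table4`, `table5`, `ancillary`.
#'
#' @param name fixture name.
#' @return data.frame.
#' @export
load_study_fixture <- function(name) {
  path <- system.file("extdata", "fixtures", paste0(name, ".csv"),
                      package = "sraholter")
  if (!nzchar(path)) stop("unknown fixture: ", name)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Confusion table from a two-row fixture
#'
#' The case row (`group != "healthy"`) supplies tp/fn, the control row
#' (`group == "healthy"`) tn/fp.
#'
#' @param fixture data.frame in the fixture schema.
#' @return a [confusion_table()].
#' @export
fixture_confusion <- function(fixture) {
  case <- fixture[fixture$group != "healthy", , drop = FALSE]
  ctrl <- fixture[fixture$group == "healthy", , drop = FALSE]
  if (nrow(case) != 1L || nrow(ctrl) != 1L)
    stop("fixture must have exactly one case and one control row")
  confusion_table(tp = case$positive, fn = case$total - case$positive,
                  fp = ctrl$total - ctrl$positive, tn = ctrl$positive)
}

#' First-hour patient-level sensitivity/specificity
#'
#' A patient counts screen-positive when the first-hour snip is classified
#' `PAF_RISK` or `AF`. Case groups contribute sensitivity, the control
#' group specificity; non-assessable patients are excluded, mirroring the
#' study's exclusions.
#'
#' @param results list of `patient_result` (see [run_patient()]).
#' @param case_groups,control_group group labels.
#' @return a `diagnostic_summary`.
#' @export
first_hour_patient_stats <- function(results,
                                     case_groups = c("PAROXYSMAL", "CHRONIC"),
                                     control_group = "HEALTHY") {
  ps <- patient_summary(results)
  ps <- ps[ps$assessable, , drop = FALSE]
  pos <- ps$first_hour_class %in% c("PAF_RISK", "AF")
  cases <- ps$group %in% case_groups
  ctrls <- ps$group %in% control_group
  sensitivity_specificity(confusion_table(
    tp = sum(pos & cases), fn = sum(!pos & cases),
    fp = sum(pos & ctrls), tn = sum(!pos & ctrls)))
}

# complete fully-sinus snips after the last AF episode, in snip order
.post_episode_snips <- function(r) {
  if (is.null(r$annotations)) return(NULL)
  af <- r$annotations[r$annotations$kind == "AF", , drop = FALSE]
  if (!nrow(af)) return(NULL)
  ep_end <- max(af$end_ms)
  s <- r$snips
  s[s$start_ms >= ep_end & s$af_truth_frac == 0 &
      s$duration_ms == 3.6e6, , drop = FALSE]
}

#' Sensitivity in the k-th sinus hour after an AF episode
#'
#' Among patients with at least one AF episode followed by at least `k`
#' complete hour-snips of sinus rhythm, the fraction whose k-th post-episode
#' sinus snip is flagged (`PAF_RISK` or `AF`). This is where heart-rate
#' dynamics that persist after an episode ends — and decay with time — show
#' up as declining sensitivity over `k`.
#'
#' @param results list of `patient_result` with annotations.
#' @param k hour offset (1, 2, 3, ...).
#' @return list with `value` (proportion; `NA` when no patient is
#'   eligible), `numerator`, `denominator`.
#' @export
post_episode_hour_sensitivity <- function(results, k = 1) {
  stopifnot(k >= 1)
  flags <- vapply(results, function(r) {
    s <- .post_episode_snips(r)
    if (is.null(s) || nrow(s) < k) return(NA)
    s$category[k] %in% c("PAF_RISK", "AF")
  }, logical(1))
  den <- sum(!is.na(flags))
  num <- sum(flags, na.rm = TRUE)
  list(value = if (den > 0) num / den else NA_real_,
       numerator = num, denominator = den)
}

#' Holter-style manifest-AF detection rate of a group
#'
#' The fraction of patients in a group with at least one annotated manifest
#' AF episode inside the window (the whole recording, or the first-hour
#' snip).
#'
#' @param results list of `patient_result` with annotations.
#' @param group group label.
#' @param window `"full"` or `"first_hour"`.
#' @return list `value`, `numerator`, `denominator` (`value` `NA` on an
#'   empty group).
#' @export
holter_detection_rate <- function(results, group,
                                  window = c("full", "first_hour")) {
  window <- match.arg(window)
  ps <- patient_summary(results)
  sel <- ps$group == group
  hit <- if (window == "full") ps$holter_af_overall else ps$holter_af_first_hour
  den <- sum(sel)
  num <- sum(hit[sel])
  list(value = if (den > 0) num / den else NA_real_,
       numerator = num, denominator = den)
}

#' Replay every printed study statistic from the packaged fixtures
#'
#' Computes, via [fixture_confusion()] and [sensitivity_specificity()], the
#' sensitivities, specificities and detection-rate ratios of the study's
#' contingency tables and results text.
#'
#' @return data.frame with `name`, `numerator`, `denominator`, `value`
#'   (proportion) and `percent`.
#' @export
study_fixture_statistics <- function() {
  out <- list()
  add <- function(name, num, den)
    out[[length(out) + 1L]] <<- data.frame(
      name = name, numerator = num, denominator = den, value = num / den,
      percent = 100 * num / den, stringsAsFactors = FALSE)
  for (tb in c("table2", "table3", "table4", "table5")) {
    ss <- sensitivity_specificity(fixture_confusion(load_study_fixture(tb)))
    add(paste0(tb, "_sensitivity"), ss$sensitivity$numerator,
        ss$sensitivity$denominator)
    add(paste0(tb, "_specificity"), ss$specificity$numerator,
        ss$specificity$denominator)
  }
  anc <- load_study_fixture("ancillary")
  for (i in seq_len(nrow(anc)))
    add(paste(anc$group[i], anc$stratum[i], sep = "_"),
        anc$positive[i], anc$total[i])
  do.call(rbind, out)
}
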