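#' Analysis configuration
#'
#' Central bag of tunable thresholds for every pipeline stage. All times are
#' milliseconds, amplitudes millivolts, frequencies hertz. Defaults follow
#' common Holter-analysis conventions; every value can be overridden by name.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details
#' QRS detection: `bp_low`/`bp_high` (Hz) delimit the detection band-pass;
#' `refractory_ms` is the minimum beat-to-beat spacing; `merge_ms` the
#' cross-lead fusion window; `quality_window_s` and `quality_agree_ms`
#' parameterize the signal-quality score (fraction of windows in which two
#' independent single-lead detectors agree).
#'
#' Beat morphology: beats wider than `wide_qrs_ms` or correlating below
#' `shape_corr_min` with the running normal template are labeled ventricular;
#' a template needs `min_template_beats` beats.
#'
#' RR features: `apen_m`, `apen_r_factor` are the approximate-entropy
#' embedding dimension and tolerance (as a multiple of the series SD);
#' `window_len` the extreme-window length; `prematurity_factor`,
#' `pac_tol`, `delayed_pause_factor`, `local_nn_k` govern the
#' premature-atrial-complex census; `min_nn_apen` / `min_nn_poincare` /
#' `min_nn_dnorm` are per-feature minimum usable interval counts.
#'
#' Analyzability gate: a snip fails with reason `NN_TOO_LOW` when it has
#' fewer than `gate_min_nn` NN intervals, `BAD_SIGNAL` when its artifact
#' fraction exceeds `gate_max_artifact`, and `PATHOLOGICAL_QRS` when its
#' ventricular-beat rate exceeds `gate_max_v_per_hour`.
#'
#' Manifest-AF rule: the dependency-free fallback detector (and the
#' regularity guard applied on top of the model) uses the dual threshold
#' `af_dnorm_sd_min` / `af_apen_min`: AF requires both high normalized
#' RR-difference dispersion and high approximate entropy, so strictly
#' alternating rhythms (bigeminy) are never called AF.
#'
#' @return a named list of class `sra_config`.
#' @export
#' @examples
#' cfg <- sra_config(wide_qrs_ms = 130)
#' cfg$wide_qrs_ms
sra_config <- function(...) {
  cfg <- list(
    # QRS detection
    bp_low = 5, bp_high = 25,
    refractory_ms = 200, merge_ms = 100,
    quality_window_s = 10, quality_agree_ms = 150,
    sat_mv = 5,
    # beat morphology
    wide_qrs_ms = 120, shape_corr_min = 0.8, min_template_beats = 30,
    # RR features
    apen_m = 2, apen_r_factor = 0.2,
    window_len = 6,
    prematurity_factor = 0.85, pac_tol = 0.10,
    reset_pause_tol = 0.15, delayed_pause_factor = 1.15, local_nn_k = 10,
    min_nn_apen = 50, min_nn_poincare = 3, min_nn_dnorm = 1,
    # analyzability gate
    gate_min_nn = 1800, gate_max_artifact = 0.20, gate_max_v_per_hour = 30,
    # manifest-AF rule / regularity guard
    af_dnorm_sd_min = 0.06, af_apen_min = 0.5,
    af_mode = "model"  # "model" or "rule"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "sra_config")
}

as_sra_config <- function(cfg) {
  if (is.null(cfg)) return(sra_config())
  if (inherits(cfg, "sra_config")) return(cfg)
  do.call(sra_config, as.list(cfg))
}

#' Read / write a configuration as JSON
#'
#' @param path file path.
#' @param cfg an [sra_config()] object.
#' @return `read_sra_config` returns an `sra_config`; `write_sra_config`
#'   returns `path` invisibly.
#' @export
read_sra_config <- function(path) {
  as_sra_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_sra_config
#' @export
write_sra_config <- function(cfg, path) {
  jsonlite::write_json(unclass(as_sra_config(cfg)), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
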