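# Seeded synthetic Holter generator: RR-level rhythm models (sinus with
# realistic HRV, AF), typed ectopy insertion, artifact marking, whole-patient
# timelines with post-episode risk dynamics, cohorts, and template ECG
# waveform synthesis. Everything is deterministic given (spec, seed).

with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483629 + 1)
}

#' Generate a sinus-rhythm RR series with realistic variability
#'
#' NN intervals are the sum of a mean cycle length, AR(1) colored noise, and
#' a sinusoidal respiratory modulation. Deviations are clipped at
#' min(2.5 SDNN, 12% of the mean cycle) — physiological sinus variability is
#' bounded, and the clip keeps ordinary sinus beats from ever crossing the
#' premature-beat threshold of the PAC census.
#'
#' @param duration_ms target duration; intervals are emitted while their
#'   cumulative sum stays within it.
#' @param mean_nn_ms mean NN interval (default 800 ms, 75 bpm).
#' @param sdnn_ms target overall SDNN (default 40 ms); 0 gives a constant
#'   series.
#' @param resp_freq_hz respiratory modulation frequency (default 0.25 Hz).
#' @param resp_frac fraction of total SDNN allocated to the respiratory
#'   component (default 0.6).
#' @param ar lag-1 autocorrelation of the colored-noise component.
#' @param seed integer seed; identical seeds give identical series.
#' @return an `rr_series` (all beats labeled N).
#' @export
gen_sinus_rr <- function(duration_ms, mean_nn_ms = 800, sdnn_ms = 40,
                         resp_freq_hz = 0.25, resp_frac = 0.6, ar = 0.8,
                         seed = NULL) {
  stopifnot(duration_ms > 0, mean_nn_ms > 0, sdnn_ms >= 0)
  with_rng(seed, {
    n <- ceiling(duration_ms / mean_nn_ms * 1.3) + 30
    if (sdnn_ms == 0) {
      iv <- rep(mean_nn_ms, n)
    } else {
      sd_ar <- sdnn_ms * sqrt(1 - resp_frac^2)
      e <- rnorm(n, 0, sd_ar * sqrt(1 - ar^2))
      x <- as.numeric(stats::filter(e, ar, method = "recursive"))
      amp <- resp_frac * sdnn_ms * sqrt(2)
      t_nom <- seq_len(n) * mean_nn_ms / 1000
      dev <- x + amp * sin(2 * pi * resp_freq_hz * t_nom + runif(1, 0, 2 * pi))
      clip <- min(2.5 * sdnn_ms, 0.12 * mean_nn_ms)
      dev <- pmin(pmax(dev, -clip), clip)
      iv <- mean_nn_ms + dev
    }
    keep <- cumsum(iv) <= duration_ms
    iv <- iv[keep]
    if (!length(iv)) iv <- mean_nn_ms
    rr_from_intervals(iv)
  })
}

#' Generate an atrial-fibrillation RR series
#'
#' Serially uncorrelated intervals from a gamma distribution with the given
#' mean and coefficient of variation — the irregularly irregular ventricular
#' response of manifest AF, without AV-node refractory modeling (a
#' documented simplification).
#'
#' @param duration_ms target duration.
#' @param mean_nn_ms mean ventricular cycle length during AF (default
#'   600 ms; AF is typically faster than the patient's sinus rhythm).
#' @param cv coefficient of variation (default 0.2; at least ~0.15 for
#'   convincing AF irregularity).
#' @param seed integer seed.
#' @return an `rr_series`.
#' @export
gen_af_rr <- function(duration_ms, mean_nn_ms = 600, cv = 0.2, seed = NULL) {
  stopifnot(duration_ms > 0, mean_nn_ms > 0, cv > 0)
  with_rng(seed, {
    n <- ceiling(duration_ms / mean_nn_ms * 1.5) + 30
    shape <- 1 / cv^2
    iv <- rgamma(n, shape = shape, rate = shape / mean_nn_ms)
    iv <- pmax(iv, 200)
    keep <- cumsum(iv) <= duration_ms
    iv <- iv[keep]
    if (!length(iv)) iv <- mean_nn_ms
    rr_from_intervals(iv)
  })
}

#' Default premature-atrial-complex type mixes
#'
#' `pac_mix_benign` is dominated by sinus-node-reset complexes (the common,
#' non-countable kind in healthy hearts); `pac_mix_risk` is dominated by the
#' countable types that feed the paroxysmal-AF risk signature.
#'
#' @format named numeric probability vectors over the four PAC types,
#'   summing to 1.
#' @export
pac_mix_benign <- c(SINUS_RESET = 0.7, FULL_COMPENSATORY = 0.1,
                    INTERPOLATED = 0.1, DELAYED_RESET = 0.1)

#' @rdname pac_mix_benign
#' @export
pac_mix_risk <- c(SINUS_RESET = 0.2, FULL_COMPENSATORY = 0.4,
                  INTERPOLATED = 0.25, DELAYED_RESET = 0.15)

# mid-tolerance (CI, P) construction per PAC type, as multiples of local NN:
# chosen so the census typing rules recover the type with margin.
.pac_geometry <- function(type, nn) {
  switch(type,
    FULL_COMPENSATORY = c(0.70, 1.30) * nn,
    INTERPOLATED      = c(0.50, 0.50) * nn,
    SINUS_RESET       = c(0.70, 1.00) * nn,
    DELAYED_RESET     = c(0.50, 1.20) * nn,
    stop("unknown PAC type: ", type))
}

# Insert ectopic beats into a beat series by replacing single intervals with
# a (coupling, pause) pair. geometry_fn(type, nn_local) -> c(ci, p).
# Returns beats + ground-truth records + number of skipped insertions.
.insert_ectopic <- function(beats, n_insert, types, geometry_fn, label,
                            width_ms, shape_corr, min_gap = 13L) {
  iv <- diff(beats$time_ms)
  lab <- beats$label
  n_iv <- length(iv)
  if (n_insert == 0L || n_iv < 2L * min_gap) {
    return(list(beats = beats, truth = NULL, skipped = n_insert))
  }
  eligible <- seq(7L, n_iv - 6L)
  ok <- vapply(eligible, function(i) all(lab[(i - 5L):(i + 6L)] == "N"),
               logical(1))
  eligible <- eligible[ok]
  pick <- integer(0)
  for (i in sample(eligible)) {
    if (length(pick) == n_insert) break
    if (!length(pick) || all(abs(pick - i) >= min_gap)) pick <- c(pick, i)
  }
  skipped <- n_insert - length(pick)
  if (!length(pick)) return(list(beats = beats, truth = NULL, skipped = skipped))
  types <- types[seq_along(pick)]
  ord <- order(pick, decreasing = TRUE)
  pick <- pick[ord]; types <- types[ord]
  truth <- vector("list", length(pick))
  iv2 <- iv; lab2 <- lab
  w2 <- beats$width_ms; a2 <- beats$amplitude_mv; c2 <- beats$shape_corr
  for (j in seq_along(pick)) {
    i <- pick[j]
    nn <- median(iv[c((i - 5L):(i - 1L), (i + 1L):(i + 5L))])
    geo <- geometry_fn(types[j], nn)
    iv2 <- append(iv2[-i], geo, after = i - 1L)
    lab2 <- append(lab2, label, after = i)
    w2 <- append(w2, width_ms, after = i)
    a2 <- append(a2, 1, after = i)
    c2 <- append(c2, shape_corr, after = i)
    truth[[j]] <- data.frame(interval_pos = i, coupling_ms = geo[1],
                             pause_ms = geo[2], local_nn_ms = nn,
                             type = types[j], stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$interval_pos), , drop = FALSE]
  # beat index after all insertions: one beat added before it per earlier pick
  truth$index <- truth$interval_pos + 1L +
    vapply(truth$interval_pos, function(p) sum(truth$interval_pos < p), 0L)
  t2 <- beats$time_ms[1] + cumsum(c(0, iv2))
  truth$time_ms <- t2[truth$index]
  out <- beat_series(t2, lab2, w2, a2, c2,
                     record_id = attr(beats, "record_id"),
                     quality_fraction = beats_quality(beats))
  rownames(truth) <- NULL
  list(beats = out, truth = truth, skipped = skipped)
}

#' Insert typed premature atrial complexes into an RR series
#'
#' Each insertion replaces one sinus interval with a coupling interval CI
#' and a pause P constructed mid-tolerance for the requested type, so the
#' [pac_census()] typing rules recover it; the inserted beat is labeled `A`
#' (narrow QRS). Insertions that cannot be placed (too close to another
#' inserted beat or a non-normal beat) are skipped and counted.
#'
#' @param rr an `rr_series` (or a [beat_series()]).
#' @param rate_per_hour expected PAC rate; the realized count is Poisson.
#' @param type_mix named probabilities over the four PAC types
#'   (`SINUS_RESET`, `FULL_COMPENSATORY`, `INTERPOLATED`, `DELAYED_RESET`),
#'   summing to 1.
#' @param seed integer seed.
#' @param cfg an [sra_config()].
#' @return list with `beats` (a `beat_series`), `truth` (ground-truth PAC
#'   records with post-insertion beat `index`, `coupling_ms`, `pause_ms`,
#'   `local_nn_ms`, `type`), and `skipped`.
#' @export
insert_pacs <- function(rr, rate_per_hour, type_mix = pac_mix_risk,
                        seed = NULL, cfg = sra_config()) {
  stopifnot(rate_per_hour >= 0, abs(sum(type_mix) - 1) < 1e-8)
  beats <- if (inherits(rr, "beat_series")) rr else rr_beats(rr)
  with_rng(seed, {
    hours <- beats_duration_ms(beats) / 3.6e6
    n <- rpois(1, rate_per_hour * hours)
    if (n == 0L) return(list(beats = beats, truth = NULL, skipped = 0L))
    types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
    .insert_ectopic(beats, n, types, .pac_geometry, label = "A",
                    width_ms = 90, shape_corr = 0.97)
  })
}

#' Insert ventricular premature beats
#'
#' Wide-QRS beats (width 180 ms, low template correlation) with a typical
#' full compensatory pause; used to exercise morphology classification and
#' the pathological-QRS analyzability gate.
#'
#' @inheritParams insert_pacs
#' @return same structure as [insert_pacs()].
#' @export
insert_vpcs <- function(rr, rate_per_hour, seed = NULL, cfg = sra_config()) {
  beats <- if (inherits(rr, "beat_series")) rr else rr_beats(rr)
  with_rng(seed, {
    hours <- beats_duration_ms(beats) / 3.6e6
    n <- rpois(1, rate_per_hour * hours)
    if (n == 0L) return(list(beats = beats, truth = NULL, skipped = 0L))
    .insert_ectopic(beats, n, rep("VPC", n),
                    function(type, nn) c(0.60, 1.40) * nn,
                    label = "V", width_ms = 180, shape_corr = 0.4)
  })
}

#' Mark a fraction of beats as artifact
#'
#' Relabels randomly chosen beats `X` (noise-corrupted detections) and sets
#' the series' clean-signal quality fraction accordingly.
#'
#' @param beats a [beat_series()].
#' @param fraction fraction of beats to mark, in `[0, 1)`.
#' @param seed integer seed.
#' @return a `beat_series`.
#' @export
mark_artifacts <- function(beats, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0 || !nrow(beats)) return(beats)
  with_rng(seed, {
    idx <- which(beats$label == "N")
    k <- round(fraction * nrow(beats))
    k <- min(k, length(idx))
    hit <- sample(idx, k)
    beats$label[hit] <- "X"
    attr(beats, "quality_fraction") <- 1 - k / nrow(beats)
    beats
  })
}

#' Rhythm timeline specification
#'
#' Describes one synthetic patient: an ordered list of rhythm segments
#' (`SINUS` / `AF`), global sinus parameters, ectopy and artifact rates, and
#' the paroxysmal-AF risk signature — the heart-rate-dynamics changes that
#' begin with an AF episode and persist, decaying, after it ends. The
#' signature is implemented as a multiplier on sinus variability and on the
#' countable-PAC rate: at a time t hours after the last AF episode ended,
#' the signature level is `base_level + (1 - base_level) * exp(-t / decay_hours)`
#' (just `base_level` before any episode).
#'
#' @param segments data.frame with columns `kind` (`"SINUS"`/`"AF"`) and
#'   `duration_ms`.
#' @param mean_nn_ms,sdnn_ms,resp_freq_hz sinus-rhythm parameters.
#' @param af_mean_nn_ms,af_cv AF-rhythm parameters.
#' @param pac_rate,pac_mix baseline (benign) PAC rate per hour and type mix.
#' @param vpc_rate ventricular ectopy per hour.
#' @param artifact_fraction fraction of beats marked artifact.
#' @param risk logical flag or a list overriding the signature parameters
#'   `sdnn_mult`, `pac_rate`, `pac_mix`, `base_level`, `decay_hours`.
#' @return object of class `rhythm_timeline`.
#' @export
rhythm_timeline <- function(segments, mean_nn_ms = 800, sdnn_ms = 40,
                            resp_freq_hz = 0.25, af_mean_nn_ms = 600,
                            af_cv = 0.2, pac_rate = 2,
                            pac_mix = pac_mix_benign, vpc_rate = 1,
                            artifact_fraction = 0.02, risk = FALSE) {
  stopifnot(is.data.frame(segments), all(segments$kind %in% c("SINUS", "AF")),
            all(segments$duration_ms > 0))
  risk_def <- list(present = FALSE, sdnn_mult = 1.6, pac_rate = 40,
                   pac_mix = pac_mix_risk, base_level = 0.1,
                   decay_hours = 1.2)
  if (isTRUE(risk)) risk <- list(present = TRUE)
  if (is.list(risk)) {
    risk_def[names(risk)] <- risk
    if (is.null(risk$present)) risk_def$present <- TRUE
  }
  structure(list(segments = segments, mean_nn_ms = mean_nn_ms,
                 sdnn_ms = sdnn_ms, resp_freq_hz = resp_freq_hz,
                 af_mean_nn_ms = af_mean_nn_ms, af_cv = af_cv,
                 pac_rate = pac_rate, pac_mix = pac_mix, vpc_rate = vpc_rate,
                 artifact_fraction = artifact_fraction, risk = risk_def),
            class = "rhythm_timeline")
}

# signature level at `hours_since_af` (NA before any episode)
risk_level <- function(risk, hours_since_af) {
  if (!risk$present) return(0)
  if (is.na(hours_since_af)) return(risk$base_level)
  risk$base_level + (1 - risk$base_level) * exp(-hours_since_af / risk$decay_hours)
}

#' Generate one synthetic patient from a rhythm timeline
#'
#' Concatenates the timeline's segments into a single annotated beat series.
#' Sinus stretches are synthesized in 30-minute blocks; when the risk
#' signature is present, each block's SDNN multiplier and countable-PAC rate
#' follow the signature level at the block's start (so sensitivity to the
#' signature decays hour by hour after an AF episode, as the screening
#' method presumes).
#'
#' @param timeline a [rhythm_timeline()].
#' @param seed integer seed.
#' @return list with `beats` (a `beat_series`), `annotations` (data.frame
#'   `start_ms,end_ms,kind` of rhythm segments), and `pacs` (ground-truth
#'   inserted-PAC table, possibly NULL).
#' @export
gen_patient <- function(timeline, seed = NULL) {
  stopifnot(inherits(timeline, "rhythm_timeline"))
  tl <- timeline
  with_rng(seed, {
    iv_all <- numeric(0); lab_all <- character(0)
    w_all <- numeric(0); c_all <- numeric(0)
    ann <- list(); pacs <- list()
    t_cursor <- 0
    last_af_end <- NA_real_
    sk <- 0L
    for (s in seq_len(nrow(tl$segments))) {
      kind <- tl$segments$kind[s]
      dur <- tl$segments$duration_ms[s]
      seg_start <- t_cursor
      if (kind == "AF") {
        rr <- gen_af_rr(dur, tl$af_mean_nn_ms, tl$af_cv,
                        seed = sub_seed(seed %||% 0, s * 101))
        iv_all <- c(iv_all, rr$interval_ms)
        lab_all <- c(lab_all, rep("N", nrow(rr)))
        w_all <- c(w_all, rep(90, nrow(rr)))
        c_all <- c(c_all, rep(0.95, nrow(rr)))
        t_cursor <- t_cursor + sum(rr$interval_ms)
        last_af_end <- t_cursor
      } else {
        block_ms <- 1.8e6
        off <- 0
        b <- 0L
        while (off < dur) {
          b <- b + 1L
          this <- min(block_ms, dur - off)
          since <- if (is.na(last_af_end)) NA_real_ else (t_cursor - last_af_end) / 3.6e6
          g <- risk_level(tl$risk, since)
          sdnn_eff <- tl$sdnn_ms * (1 + (tl$risk$sdnn_mult - 1) * g)
          pac_eff <- tl$pac_rate + tl$risk$pac_rate * g
          mix <- if (g > 0.05) tl$risk$pac_mix else tl$pac_mix
          rr <- gen_sinus_rr(this, tl$mean_nn_ms, sdnn_eff, tl$resp_freq_hz,
                             seed = sub_seed(seed %||% 0, s * 101 + b))
          ins <- insert_pacs(rr, pac_eff, mix,
                             seed = sub_seed(seed %||% 0, s * 101 + b + 5000))
          sk <- sk + ins$skipped
          ins2 <- insert_vpcs(ins$beats, tl$vpc_rate,
                              seed = sub_seed(seed %||% 0, s * 101 + b + 9000))
          bts <- ins2$beats
          if (!is.null(ins$truth)) {
            tr <- ins$truth
            tr$time_ms <- tr$time_ms + t_cursor
            pacs[[length(pacs) + 1L]] <- tr
          }
          iv_seg <- diff(bts$time_ms)
          iv_all <- c(iv_all, iv_seg, tl$mean_nn_ms)  # bridge interval
          lab_all <- c(lab_all, bts$label[-1L])
          w_all <- c(w_all, bts$width_ms[-1L])
          c_all <- c(c_all, bts$shape_corr[-1L])
          lab_all <- c(lab_all, "N"); w_all <- c(w_all, 90); c_all <- c(c_all, 0.97)
          t_cursor <- t_cursor + sum(iv_seg) + tl$mean_nn_ms
          off <- off + this
        }
      }
      ann[[s]] <- data.frame(start_ms = seg_start, end_ms = t_cursor,
                             kind = kind, stringsAsFactors = FALSE)
    }
    t <- cumsum(c(0, iv_all))
    lab <- c("N", lab_all)
    w <- c(90, w_all); cc <- c(0.97, c_all)
    beats <- beat_series(t, lab, w, 1, cc, quality_fraction = 1)
    beats <- mark_artifacts(beats, tl$artifact_fraction,
                            seed = sub_seed(seed %||% 0, 77777))
    annotations <- do.call(rbind, ann)
    # merge adjacent annotations of equal kind
    list(beats = beats, annotations = annotations,
         pacs = if (length(pacs)) do.call(rbind, pacs) else NULL,
         skipped_insertions = sk)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort specification
#'
#' Group sizes and recording parameters of a synthetic study cohort. The
#' default is a desk-scale cohort (10 paroxysmal / 3 chronic / 15 healthy,
#' 6-hour recordings); `study_scale = TRUE` switches to the full study
#' structure (70/19/100, 20-24 h).
#'
#' @param n_paroxysmal,n_chronic,n_healthy patients per group.
#' @param duration_range_h recording duration range in hours.
#' @param episode_prob probability a paroxysmal patient has manifest AF
#'   episodes within the recording (the study found manifest AF in 27% of
#'   its paroxysmal group over full recordings).
#' @param burden_range AF-burden range (fraction of recording in AF) for
#'   paroxysmal patients who do have episodes.
#' @param study_scale use the full study group sizes and 20-24 h durations.
#' @param seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_paroxysmal = 10, n_chronic = 3, n_healthy = 15,
                        duration_range_h = c(6, 6), episode_prob = 0.3,
                        burden_range = c(0.05, 0.3), study_scale = FALSE,
                        seed = 1) {
  if (study_scale) {
    n_paroxysmal <- 70; n_chronic <- 19; n_healthy <- 100
    duration_range_h <- c(20, 24)
  }
  stopifnot(n_paroxysmal >= 0, n_chronic >= 0, n_healthy >= 0,
            all(burden_range >= 0), all(burden_range < 1))
  structure(list(n_paroxysmal = n_paroxysmal, n_chronic = n_chronic,
                 n_healthy = n_healthy, duration_range_h = duration_range_h,
                 episode_prob = episode_prob, burden_range = burden_range,
                 seed = seed),
            class = "cohort_spec")
}

# build the rhythm timeline for one cohort patient
.cohort_timeline <- function(group, duration_ms, u) {
  if (group == "CHRONIC") {
    segs <- data.frame(kind = "AF", duration_ms = duration_ms)
    return(rhythm_timeline(segs, vpc_rate = 2))
  }
  if (group == "HEALTHY") {
    segs <- data.frame(kind = "SINUS", duration_ms = duration_ms)
    return(rhythm_timeline(segs, mean_nn_ms = 750 + 100 * u[1],
                           sdnn_ms = 30 + 20 * u[2]))
  }
  # paroxysmal: risk signature always; episodes with probability episode_prob
  has_ep <- u[3] < u[4]  # u[4] carries episode_prob
  if (!has_ep) {
    segs <- data.frame(kind = "SINUS", duration_ms = duration_ms)
  } else {
    burden <- u[5]
    ep_ms <- max(6e5, burden * duration_ms)
    pre <- max(3.6e5, (duration_ms - ep_ms) * u[6])
    post <- duration_ms - pre - ep_ms
    if (post < 3.6e5) { post <- 3.6e5; pre <- duration_ms - ep_ms - post }
    segs <- data.frame(kind = c("SINUS", "AF", "SINUS"),
                       duration_ms = c(pre, ep_ms, post))
  }
  rhythm_timeline(segs, mean_nn_ms = 760 + 80 * u[1], sdnn_ms = 32 + 16 * u[2],
                  risk = list(present = TRUE, base_level = 0.5))
}

#' Generate a synthetic study cohort
#'
#' Produces one annotated patient per cohort slot, reproducibly from the
#' master seed, together with a manifest consumable by [run_patient()] /
#' [run_cohort()]. Recording start clock times are drawn at whole minutes
#' between 08:00 and 16:00 (Holter hookups happen during office hours, and
#' the study's offset convention is minute-resolved).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, per-patient beats and
#'   annotation CSVs plus `manifest.json` are written there.
#' @return list with `manifest` (data.frame: `pseudonym`, `group`,
#'   `start_clock_s`, `duration_ms`) and `patients` (named list of
#'   [gen_patient()] outputs).
#' @export
gen_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(c("PAROXYSMAL", "CHRONIC", "HEALTHY"),
                c(spec$n_paroxysmal, spec$n_chronic, spec$n_healthy))
  patients <- list(); rows <- list()
  for (i in seq_along(groups)) {
    si <- sub_seed(spec$seed, i)
    u <- with_rng(si, runif(8))
    u[4] <- spec$episode_prob
    u[5] <- spec$burden_range[1] + u[5] * diff(spec$burden_range)
    dur_h <- spec$duration_range_h[1] +
      u[7] * diff(spec$duration_range_h)
    duration_ms <- round(dur_h * 3.6e6)
    tl <- .cohort_timeline(groups[i], duration_ms, u)
    pat <- gen_patient(tl, seed = sub_seed(spec$seed, 1000 + i))
    ps <- pseudonym_for(sprintf("synthetic-%03d", i), salt = spec$seed)
    start_clock_s <- 60 * (8 * 60 + floor(u[8] * 8 * 60))  # 08:00-16:00
    patients[[ps]] <- pat
    rows[[i]] <- data.frame(pseudonym = ps, group = groups[i],
                            start_clock_s = start_clock_s,
                            duration_ms = beats_duration_ms(pat$beats),
                            stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pseudonym = character(0), group = character(0),
               start_clock_s = numeric(0), duration_ms = numeric(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$beats_csv <- NA_character_; manifest$annotations_csv <- NA_character_
    for (i in seq_len(nrow(manifest))) {
      ps <- manifest$pseudonym[i]
      bf <- file.path(out_dir, paste0(ps, "-beats.csv"))
      af <- file.path(out_dir, paste0(ps, "-annotations.csv"))
      write_beats_csv(patients[[ps]]$beats, bf)
      write.csv(patients[[ps]]$annotations, af, row.names = FALSE)
      manifest$beats_csv[i] <- basename(bf)
      manifest$annotations_csv[i] <- basename(af)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = I(17))
  }
  list(manifest = manifest, patients = patients)
}

#' Synthesize an ECG waveform from a beat series
#'
#' Template-based synthesis: each beat contributes Gaussian P-QRS-T bumps
#' (ventricular beats get a wide, P-less template), replicated over `n_leads`
#' leads with distinct gains, plus white noise at the requested SNR. R-peak
#' times are preserved to within one sample.
#'
#' @param beats a [beat_series()].
#' @param fs sampling rate in Hz (at least 100).
#' @param snr_db signal-to-noise ratio of the additive noise.
#' @param n_leads number of leads (1-3).
#' @param seed integer seed.
#' @return an [ecg_record()].
#' @export
gen_ecg_waveform <- function(beats, fs = 250, snr_db = 20, n_leads = 3,
                             seed = NULL) {
  stopifnot(fs >= 100, n_leads >= 1, n_leads <= 3)
  with_rng(seed, {
    dur_s <- beats_duration_ms(beats) / 1000 + 1
    n <- ceiling(dur_s * fs)
    tt <- (seq_len(n) - 1) / fs * 1000  # ms
    base <- numeric(n)
    add_bump <- function(x, center_ms, amp, sigma_ms) {
      i0 <- max(1L, floor((center_ms - 4 * sigma_ms) / 1000 * fs) + 1L)
      i1 <- min(n, ceiling((center_ms + 4 * sigma_ms) / 1000 * fs) + 1L)
      if (i1 < i0) return(x)
      idx <- i0:i1
      x[idx] <- x[idx] + amp * exp(-0.5 * ((tt[idx] - center_ms) / sigma_ms)^2)
      x
    }
    for (k in seq_len(nrow(beats))) {
      tc <- beats$time_ms[k]
      if (beats$label[k] == "V") {
        base <- add_bump(base, tc, 1.5, 28)           # wide, tall QRS
        base <- add_bump(base, tc + 300, -0.25, 70)   # discordant T
      } else {
        base <- add_bump(base, tc - 160, 0.1, 20)     # P
        base <- add_bump(base, tc, 1.0, 12)           # QRS
        base <- add_bump(base, tc + 40, -0.15, 15)    # S
        base <- add_bump(base, tc + 260, 0.25, 55)    # T
      }
    }
    p_sig <- mean(base^2)
    noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
    gains <- c(1, 0.8, 0.65)[seq_len(n_leads)]
    leads <- lapply(gains, function(g) g * base + rnorm(n, 0, noise_sd))
    ecg_record(leads, fs, metadata = list(record_id = attr(beats, "record_id")))
  })
}
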