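# ECG amplitude-signature pipeline: R-peak detection (band-passed
# squared-derivative energy with an adaptive threshold), artifact-free
# per-lead beat averaging, amplitude measurement (R and P against the PR
# baseline, RS as R-to-S excursion, T against the first plateau-like shape
# preceding the T peak), and the Ekappa score
#   Ekappa = alpha * (T_aVL / RS_aVL - R_III / RS_Vmax).

#' Detect heart beats and flag artifact-corrupted ones
#'
#' R peaks are located on a reference lead by band-passing (5--15 Hz),
#' squaring the derivative, integrating over a 150 ms window and
#' thresholding adaptively, with a 250 ms refractory period. A beat is
#' flagged as artifact when its waveform correlates with the median beat
#' template below `artifact_corr_min`, when its R amplitude deviates from
#' the median by more than `artifact_mad_mult` MADs, or when its full
#' cycle window falls outside the recording.
#'
#' @param rec an `ecg_recording` of at least 10 s.
#' @param reference_lead lead used for detection (default "II").
#' @param artifact_corr_min template-correlation threshold (default 0.9).
#' @param artifact_mad_mult MAD multiplier for the R-amplitude rule.
#' @return a `beat_annotations` object: `r_peaks` (sample indices),
#'   per-beat `p_idx`, `s_idx`, `t_idx`, `artifact_flags`, `median_rr_s`.
#' @export
detect_beats <- function(rec, reference_lead = "II",
                         artifact_corr_min = 0.9, artifact_mad_mult = 3) {
  stopifnot(inherits(rec, "ecg_recording"))
  fs <- rec$sampling_hz
  stop_if(nrow(rec$samples) < 10 * fs, "recording must be at least 10 s")
  v <- rec$samples[, reference_lead]

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, v)
  e <- c(0, diff(f))^2
  w <- max(3L, round(0.150 * fs))
  cs <- cumsum(c(0, e))
  half <- w %/% 2
  lo_i <- pmax(seq_along(e) - half, 0L)
  hi_i <- pmin(seq_along(e) + (w - half - 1L), length(e))
  e <- (cs[hi_i + 1L] - cs[lo_i + 1L]) / w

  thr <- 0.30 * quantile(e, 0.99)
  stop_if(!is.finite(thr) || thr <= 0, "no detectable beats")
  above <- e > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- mapply(function(s, q) s - 1 + which.max(e[s:q]),
                 starts[runs$values], ends[runs$values])
  stop_if(length(cand) == 0, "no detectable beats")
  # refractory merge: drop candidates within 250 ms of a stronger one
  refr <- round(0.250 * fs)
  keep <- logical(length(cand))
  ord <- order(e[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!any(abs(cand[i] - taken) < refr)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])

  # refine R on the raw reference lead
  hw <- round(0.075 * fs)
  r_peaks <- vapply(cand, function(ci) {
    a <- max(1L, ci - hw); b <- min(length(v), ci + hw)
    a - 1L + which.max(v[a:b])
  }, numeric(1))
  r_peaks <- sort(unique(r_peaks))
  stop_if(length(r_peaks) == 0, "no detectable beats")

  rr <- diff(r_peaks) / fs
  med_rr <- if (length(rr)) median(rr) else nrow(rec$samples) / fs
  bpm <- 60 / med_rr
  if (bpm < 30 || bpm > 200)
    warning(sprintf("heart rate %.0f bpm outside 30-200 bpm", bpm))

  win <- function(idx, lo_s, hi_s) {
    a <- idx + round(lo_s * fs); b <- idx + round(hi_s * fs)
    if (a < 1 || b > length(v)) return(NA_integer_)
    c(a, b)
  }
  pick <- function(idx, lo_s, hi_s, fun) {
    wb <- win(idx, lo_s, hi_s)
    if (anyNA(wb)) return(NA_real_)
    wb[1] - 1 + fun(v[wb[1]:wb[2]])
  }
  s_idx <- vapply(r_peaks, pick, numeric(1), 0.005, 0.080, which.min)
  t_idx <- vapply(r_peaks, pick, numeric(1), 0.150, 0.450,
                  function(x) which.max(abs(x)))
  p_idx <- vapply(r_peaks, pick, numeric(1), -0.250, -0.100,
                  function(x) which.max(abs(x)))

  # artifact criteria on the full-cycle segment of the reference lead
  lo <- round(0.45 * med_rr * fs); hi <- round(0.55 * med_rr * fs) - 1
  n_beats <- length(r_peaks)
  in_range <- r_peaks - lo >= 1 & r_peaks + hi <= length(v)
  seg <- matrix(NA_real_, lo + hi + 1, n_beats)
  for (b in which(in_range)) seg[, b] <- v[(r_peaks[b] - lo):(r_peaks[b] + hi)]
  flags <- !in_range
  if (sum(in_range) >= 2) {
    templ <- apply(seg[, in_range, drop = FALSE], 1, median)
    if (sd(templ) > 0) {
      cc <- suppressWarnings(cor(seg[, in_range, drop = FALSE], templ))
      cc[is.na(cc)] <- 0
      flags[in_range] <- flags[in_range] | cc < artifact_corr_min
    }
    r_amp <- v[r_peaks]
    dev <- abs(r_amp - median(r_amp[in_range]))
    tol <- artifact_mad_mult * mad(r_amp[in_range])
    if (tol > 0) flags <- flags | dev > tol
  }

  structure(list(r_peaks = r_peaks, p_idx = p_idx, s_idx = s_idx,
                 t_idx = t_idx, artifact_flags = flags,
                 reference_lead = reference_lead, median_rr_s = med_rr,
                 sampling_hz = fs),
            class = "beat_annotations")
}

#' Average artifact-free beats per lead
#'
#' Unflagged beats are aligned on the reference-lead R peak (the same
#' alignment index for every lead, so lead identities survive averaging)
#' and averaged pointwise over a full cycle window of
#' `[-0.45, +0.55) * median RR`.
#'
#' @param rec an `ecg_recording`.
#' @param ann matching [detect_beats()] annotations.
#' @return an `averaged_cycle`: `waveform` (cycle-samples x 12 matrix, mV),
#'   `r_index` (alignment sample within the cycle), `sampling_hz`,
#'   `n_beats_averaged`.
#' @export
average_beats <- function(rec, ann) {
  stopifnot(inherits(rec, "ecg_recording"), inherits(ann, "beat_annotations"))
  fs <- rec$sampling_hz
  lo <- round(0.45 * ann$median_rr_s * fs)
  hi <- round(0.55 * ann$median_rr_s * fs) - 1
  use <- !ann$artifact_flags &
    ann$r_peaks - lo >= 1 & ann$r_peaks + hi <= nrow(rec$samples)
  stop_if(!any(use), "all beats flagged as artifacts")
  idx <- ann$r_peaks[use]
  avg <- matrix(0, lo + hi + 1, ncol(rec$samples),
                dimnames = list(NULL, colnames(rec$samples)))
  for (r in idx) avg <- avg + rec$samples[(r - lo):(r + hi), ]
  avg <- avg / length(idx)
  structure(list(waveform = avg, r_index = lo + 1L, sampling_hz = fs,
                 n_beats_averaged = length(idx)),
            class = "averaged_cycle")
}

#' Measure P, R, RS and T amplitudes on an averaged cycle
#'
#' Per lead: the isoelectric baseline is the mean of a 40 ms PR-segment
#' window ending 20 ms before QRS onset (taken as 40 ms before the R peak);
#' R (and P) amplitudes are measured against this baseline; RS is the
#' R-peak-to-S-trough excursion; T is measured against the first
#' plateau-like interval preceding the T peak, defined as the earliest
#' window of at least `plateau_win_ms` after the QRS in which the absolute
#' slope stays below `plateau_slope_max` microvolts/ms. If no plateau is
#' found the PR baseline is used and a warning emitted.
#'
#' @param cyc an [average_beats()] result.
#' @param plateau_win_ms minimum plateau window width, ms (default 20).
#' @param plateau_slope_max plateau slope bound, microvolts per ms
#'   (default 2.5).
#' @return a `wave_amplitudes` 12 x 4 matrix (lead x P/R/RS/T), absolute
#'   values in mV.
#' @export
measure_amplitudes <- function(cyc, plateau_win_ms = 20,
                               plateau_slope_max = 2.5) {
  stopifnot(inherits(cyc, "averaged_cycle"))
  fs <- cyc$sampling_hz
  ms <- function(x) round(x / 1000 * fs)
  r0 <- cyc$r_index
  n <- nrow(cyc$waveform)
  out <- matrix(0, 12, 4, dimnames = list(LEAD_NAMES, c("P", "R", "RS", "T")))
  for (nm in LEAD_NAMES) {
    v <- cyc$waveform[, nm]
    base_win <- max(1, r0 - ms(100)):max(1, r0 - ms(60))
    baseline <- mean(v[base_win])
    qrs <- max(1, r0 - ms(20)):min(n, r0 + ms(20))
    r_pk <- qrs[which.max(v[qrs])]
    r_val <- v[r_pk]
    s_win <- min(n, r_pk + 1):min(n, r0 + ms(80))
    s_val <- min(v[s_win])
    p_win <- max(1, r0 - ms(250)):max(1, r0 - ms(100))
    p_amp <- max(abs(v[p_win] - baseline))
    t_win <- min(n, r0 + ms(150)):min(n, r0 + ms(450))
    t_pk <- t_win[which.max(abs(v[t_win] - baseline))]
    t_val <- v[t_pk]
    # plateau search between QRS end and the T peak
    plat_start <- r0 + ms(80)
    level <- baseline
    found <- FALSE
    if (t_pk - plat_start >= ms(plateau_win_ms)) {
      seg <- plat_start:t_pk
      slope <- abs(diff(v[seg])) * fs / 1000  # microvolts per ms
      ok <- slope < plateau_slope_max
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      good <- which(r$values & r$lengths >= ms(plateau_win_ms))
      if (length(good)) {
        a <- seg[starts[good[1]]]
        level <- mean(v[a:(a + ms(plateau_win_ms))])
        found <- TRUE
      }
    }
    if (!found && sd(v) > 0)
      warning(sprintf("no pre-T plateau found for lead %s; using PR baseline",
                      nm))
    out[nm, ] <- c(P = p_amp, R = abs(r_val - baseline),
                   RS = abs(r_val - s_val), T = abs(t_val - level))
  }
  structure(out, class = c("wave_amplitudes", class(out)))
}

#' Assemble the four Ekappa inputs from per-lead amplitudes
#'
#' @param amps a [measure_amplitudes()] 12 x 4 matrix.
#' @param alpha dimensionless scale factor (default 10).
#' @return an `ekappa_inputs` list: `T_aVL`, `RS_aVL`, `R_III`, `RS_Vmax`
#'   (mV) and `alpha`.
#' @export
assemble_ekappa_inputs <- function(amps, alpha = 10) {
  chest <- paste0("V", 1:6)
  stop_if(!all(c("aVL", "III", chest) %in% rownames(amps)),
          "missing required leads (aVL, III, V1-V6)")
  inputs <- list(T_aVL = amps["aVL", "T"], RS_aVL = amps["aVL", "RS"],
                 R_III = amps["III", "R"],
                 RS_Vmax = max(amps[chest, "RS"]), alpha = alpha)
  structure(inputs, class = "ekappa_inputs")
}

#' Compute the Ekappa cardiac amplitude signature
#'
#' `Ekappa = alpha * (T_aVL / RS_aVL - R_III / RS_Vmax)`: the ratio of the
#' aVL T-wave to the aVL RS excursion, minus the ratio of the lead III
#' R-wave to the maximal chest-lead RS excursion, scaled by `alpha`
#' (default 10) for readability. Exactly linear in `alpha`.
#'
#' @param inputs an [assemble_ekappa_inputs()] object (or a list with the
#'   same fields).
#' @param subject_id optional identifier carried through.
#' @return an `ekappa_result` list: `ekappa`, `inputs`, `subject_id`.
#' @export
compute_ekappa <- function(inputs, subject_id = NA_character_) {
  stop_if(!all(c("T_aVL", "RS_aVL", "R_III", "RS_Vmax", "alpha") %in%
                 names(inputs)), "incomplete Ekappa inputs")
  stop_if(inputs$RS_aVL <= 0 || inputs$RS_Vmax <= 0,
          "zero or negative denominator (RS_aVL, RS_Vmax)")
  stop_if(inputs$alpha <= 0, "alpha must be > 0")
  ek <- inputs$alpha *
    (inputs$T_aVL / inputs$RS_aVL - inputs$R_III / inputs$RS_Vmax)
  structure(list(ekappa = ek, inputs = inputs, subject_id = subject_id),
            class = "ekappa_result")
}

#' Full per-recording Ekappa pipeline
#'
#' Convenience composition: [detect_beats()] -> [average_beats()] ->
#' [measure_amplitudes()] -> [assemble_ekappa_inputs()] ->
#' [compute_ekappa()].
#'
#' @inheritParams detect_beats
#' @inheritParams assemble_ekappa_inputs
#' @param subject_id optional identifier.
#' @return an `ekappa_result` with the intermediate `amplitudes` and
#'   `n_beats_averaged` attached.
#' @export
ekappa_pipeline <- function(rec, alpha = 10, subject_id = NA_character_) {
  ann <- detect_beats(rec)
  cyc <- average_beats(rec, ann)
  amps <- measure_amplitudes(cyc)
  res <- compute_ekappa(assemble_ekappa_inputs(amps, alpha = alpha),
                        subject_id = subject_id)
  res$amplitudes <- amps
  res$n_beats_averaged <- cyc$n_beats_averaged
  res
}
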