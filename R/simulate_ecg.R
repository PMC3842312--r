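# Synthetic 12-lead ECG generator.
#
# Limb leads are never drawn independently: three electrode potentials
# (RA, LA, LL) are simulated and the six extremity leads derived from them,
# so the Einthoven/Goldberger identities (III = II - I, aVL = I - II/2,
# aVR = -(I + II)/2, aVF = II - I/2) hold to machine precision, noise
# included. The six chest leads are simulated directly. Each beat is a sum
# of asymmetric Gaussian bumps (P, R, S, T) plus a constant ST plateau with
# smooth edges; the T bump rides on the plateau so the "T relative to the
# preceding plateau" measurement convention is exercisable.

# Wave timing constants, seconds relative to the R peak.
.WAVE_TIMING <- list(
  P = c(mu = -0.170, sl = 0.020, sr = 0.020),
  R = c(mu =  0.000, sl = 0.012, sr = 0.012),
  S = c(mu =  0.035, sl = 0.010, sr = 0.010),
  T = c(mu =  0.260, sl = 0.035, sr = 0.045)
)
# ST plateau: cosine ramp 0.050-0.075 s, flat to 0.30 s, ramp down by 0.38 s.
.ST_EDGES <- c(up0 = 0.050, up1 = 0.075, down0 = 0.30, down1 = 0.38)
# Nominal T amplitude to which st_offset_mv refers (see ecg_gen_params).
.ST_REF_T <- 0.3

# Default per-waveform peak amplitudes (mV): three electrode potentials and
# six chest leads, columns P, R, S, T. Chosen to give physiologically
# plausible derived leads (small aVL, negative aVR QRS, precordial RS
# progression with RS maximal around V4).
.DEFAULT_AMPLITUDES <- function() {
  electrodes <- rbind(
    RA = c(P = -0.05, R = -0.50, S =  0.10, T = -0.15),
    LA = c(P =  0.03, R =  0.30, S = -0.05, T =  0.10),
    LL = c(P =  0.08, R =  0.90, S = -0.15, T =  0.25))
  chest <- rbind(
    V1 = c(P = 0.05, R = 0.20, S = -1.00, T = -0.10),
    V2 = c(P = 0.05, R = 0.40, S = -1.20, T =  0.30),
    V3 = c(P = 0.06, R = 0.80, S = -0.80, T =  0.40),
    V4 = c(P = 0.07, R = 1.50, S = -0.40, T =  0.45),
    V5 = c(P = 0.08, R = 1.60, S = -0.20, T =  0.40),
    V6 = c(P = 0.08, R = 1.30, S = -0.10, T =  0.35))
  list(electrodes = electrodes, chest = chest)
}

#' Parameters for the synthetic 12-lead ECG generator
#'
#' @param heart_rate_bpm heart rate in beats per minute (> 0).
#' @param duration_s recording duration in seconds (> 0).
#' @param sampling_hz sampling rate in samples per second (>= 250).
#' @param lead_amplitudes list with `electrodes` (3 x 4 matrix, rows RA, LA,
#'   LL) and `chest` (6 x 4 matrix, rows V1--V6), columns P, R, S, T: peak
#'   amplitudes in mV of the constituent waveforms. Extremity leads are
#'   derived from the electrode potentials.
#' @param st_offset_mv plateau level, in mV, of a waveform whose T amplitude
#'   is the nominal 0.3 mV; other waveforms scale proportionally to their T
#'   amplitude so the plateau survives the linear lead derivations.
#' @param noise_sd_mv additive white-noise SD in mV, applied to each
#'   electrode potential and chest lead (>= 0).
#' @param artifact_beats integer beat indices to corrupt with a large
#'   motion-like transient.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an object of class `ecg_gen_params`.
#' @export
ecg_gen_params <- function(heart_rate_bpm = 60, duration_s = 120,
                           sampling_hz = 1000,
                           lead_amplitudes = .DEFAULT_AMPLITUDES(),
                           st_offset_mv = 0.1, noise_sd_mv = 0,
                           artifact_beats = integer(0), seed = NULL) {
  stop_if(heart_rate_bpm <= 0, "heart_rate_bpm must be > 0")
  stop_if(duration_s <= 0, "duration_s must be > 0")
  stop_if(sampling_hz < 250, "sampling_hz must be >= 250")
  stop_if(noise_sd_mv < 0, "noise_sd_mv must be >= 0")
  amps <- rbind(lead_amplitudes$electrodes, lead_amplitudes$chest)
  stop_if(any(!is.finite(amps)), "non-finite wave amplitudes")
  structure(list(heart_rate_bpm = heart_rate_bpm, duration_s = duration_s,
                 sampling_hz = sampling_hz, lead_amplitudes = lead_amplitudes,
                 st_offset_mv = st_offset_mv, noise_sd_mv = noise_sd_mv,
                 artifact_beats = as.integer(artifact_beats), seed = seed),
            class = "ecg_gen_params")
}

# Asymmetric Gaussian bump, evaluated only on its 8-sigma support.
.bump <- function(t, mu, sl, sr, amp) {
  out <- numeric(length(t))
  idx <- which(t > mu - 8 * sl & t < mu + 8 * sr)
  if (length(idx)) {
    ti <- t[idx]
    s <- rep(sr, length(ti))
    s[ti < mu] <- sl
    out[idx] <- amp * exp(-(ti - mu)^2 / (2 * s^2))
  }
  out
}

# Smooth 0-1 plateau window (cosine ramps).
.plateau_shape <- function(t) {
  e <- .ST_EDGES
  w <- numeric(length(t))
  up <- t >= e["up0"] & t < e["up1"]
  w[up] <- 0.5 - 0.5 * cos(pi * (t[up] - e["up0"]) / (e["up1"] - e["up0"]))
  w[t >= e["up1"] & t <= e["down0"]] <- 1
  dn <- t > e["down0"] & t < e["down1"]
  w[dn] <- 0.5 + 0.5 * cos(pi * (t[dn] - e["down0"]) / (e["down1"] - e["down0"]))
  w
}

# Unit-amplitude wave shapes at times `rel` (s) relative to the R peak:
# columns P, R, S, T bumps and the ST plateau window. Shared by all source
# waveforms, so a recording is one shapes %*% weights product.
.beat_shapes <- function(rel) {
  tm <- .WAVE_TIMING
  cbind(P = .bump(rel, tm$P[["mu"]], tm$P[["sl"]], tm$P[["sr"]], 1),
        R = .bump(rel, tm$R[["mu"]], tm$R[["sl"]], tm$R[["sr"]], 1),
        S = .bump(rel, tm$S[["mu"]], tm$S[["sl"]], tm$S[["sr"]], 1),
        T = .bump(rel, tm$T[["mu"]], tm$T[["sl"]], tm$T[["sr"]], 1),
        ST = .plateau_shape(rel))
}

# Per-source weights for the shape columns: P/R/S/T amplitudes plus the
# T-proportional plateau level.
.shape_weights <- function(amps_matrix, st_offset_mv) {
  rbind(t(amps_matrix[, c("P", "R", "S", "T"), drop = FALSE]),
        ST = st_offset_mv * amps_matrix[, "T"] / .ST_REF_T)
}

# One noiseless beat of a single source waveform (ground-truth evaluation).
.beat_waveform <- function(rel, amps, st_offset_mv) {
  as.numeric(.beat_shapes(rel) %*%
               .shape_weights(matrix(amps, 1,
                                     dimnames = list(NULL, names(amps))),
                              st_offset_mv))
}

#' Simulate a 12-lead ECG recording
#'
#' The noiseless output is exactly periodic with period `60 / heart_rate_bpm`
#' s; R peaks sit at `(k - 0.55) * period` for beats `k = 1, 2, ...`, so a
#' 120 s recording at 60 bpm contains exactly 120 complete cardiac cycles.
#' Beats listed in `artifact_beats` receive a large asymmetric transient
#' (different amplitude per electrode, so it survives the lead derivations).
#'
#' @param params an [ecg_gen_params()] object.
#' @return an `ecg_recording`: list with `samples` (time x 12 matrix, mV,
#'   columns in canonical lead order), `lead_names`, `sampling_hz`, and
#'   ground-truth attributes `r_times` (true R-peak times, s) and `params`.
#' @export
simulate_ecg <- function(params) {
  stopifnot(inherits(params, "ecg_gen_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_hz
  period <- 60 / params$heart_rate_bpm
  n_beats <- floor(params$duration_s / period + 1e-9)
  stop_if(n_beats < 1, "duration shorter than one cardiac cycle")
  n <- round(params$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # phase in [-0.45, 0.55) * period relative to the nearest R peak
  rel <- (((t / period) %% 1) - 0.45) * period

  amps <- rbind(params$lead_amplitudes$electrodes, params$lead_amplitudes$chest)
  src <- .beat_shapes(rel) %*% .shape_weights(amps, params$st_offset_mv)
  colnames(src) <- rownames(amps)

  r_times <- (seq_len(n_beats) - 0.55) * period
  for (b in params$artifact_beats) {
    if (b < 1 || b > n_beats) next
    centre <- r_times[b] + 0.10
    shape <- .bump(t, centre, 0.05, 0.09, 1)
    art <- c(RA = 4, LA = -3, LL = 2, V1 = 3.5, V2 = -2.5, V3 = 3,
             V4 = -3.5, V5 = 2.5, V6 = -3)
    src <- src + outer(shape, art[colnames(src)])
  }
  if (params$noise_sd_mv > 0)
    src <- src + matrix(rnorm(length(src), sd = params$noise_sd_mv), nrow(src))

  leads <- cbind(
    I   = src[, "LA"] - src[, "RA"],
    II  = src[, "LL"] - src[, "RA"],
    III = src[, "LL"] - src[, "LA"],
    aVR = src[, "RA"] - (src[, "LA"] + src[, "LL"]) / 2,
    aVL = src[, "LA"] - (src[, "RA"] + src[, "LL"]) / 2,
    aVF = src[, "LL"] - (src[, "RA"] + src[, "LA"]) / 2,
    src[, c("V1", "V2", "V3", "V4", "V5", "V6")])
  ecg_recording(leads, sampling_hz = fs, r_times = r_times, params = params)
}

#' Construct an ECG recording object
#'
#' @param samples time x lead numeric matrix in mV with lead-name columns.
#' @param sampling_hz sampling rate, samples/s.
#' @param r_times optional ground-truth R-peak times (generator side).
#' @param params optional generator parameters.
#' @export
ecg_recording <- function(samples, sampling_hz, r_times = NULL, params = NULL) {
  stop_if(!all(LEAD_NAMES %in% colnames(samples)),
          "all twelve standard leads must be present")
  stop_if(any(!is.finite(samples)), "non-finite samples")
  stop_if(sampling_hz <= 0, "sampling_hz must be > 0")
  structure(list(samples = samples[, LEAD_NAMES, drop = FALSE],
                 lead_names = LEAD_NAMES, sampling_hz = sampling_hz),
            r_times = r_times, params = params, class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d leads, %d samples at %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_hz,
              nrow(x$samples) / x$sampling_hz))
  invisible(x)
}

#' Ground-truth wave amplitudes of the noiseless generator beat
#'
#' Evaluates one noiseless cardiac cycle per lead on a dense grid and reads
#' off the amplitudes under the measurement conventions: P and R relative to
#' the true zero baseline, RS as the R-peak-to-S-trough excursion within the
#' QRS window, T as the (known) T-bump amplitude relative to the plateau.
#' Independent of the detection/averaging/measurement pipeline.
#'
#' @param params an [ecg_gen_params()] object.
#' @return 12 x 4 matrix (lead x P/R/RS/T), absolute values, mV.
#' @export
ecg_ground_truth <- function(params) {
  fs_dense <- 4000
  period <- 60 / params$heart_rate_bpm
  rel <- seq(-0.45 * period, 0.55 * period, by = 1 / fs_dense)
  amps <- rbind(params$lead_amplitudes$electrodes, params$lead_amplitudes$chest)
  src <- sapply(rownames(amps), function(nm)
    .beat_waveform(rel, amps[nm, ], params$st_offset_mv))
  leads <- cbind(
    I   = src[, "LA"] - src[, "RA"],
    II  = src[, "LL"] - src[, "RA"],
    III = src[, "LL"] - src[, "LA"],
    aVR = src[, "RA"] - (src[, "LA"] + src[, "LL"]) / 2,
    aVL = src[, "LA"] - (src[, "RA"] + src[, "LL"]) / 2,
    aVF = src[, "LL"] - (src[, "RA"] + src[, "LA"]) / 2,
    src[, c("V1", "V2", "V3", "V4", "V5", "V6")])
  lead_t <- c(I   = amps["LA", "T"] - amps["RA", "T"],
              II  = amps["LL", "T"] - amps["RA", "T"],
              III = amps["LL", "T"] - amps["LA", "T"],
              aVR = amps["RA", "T"] - (amps["LA", "T"] + amps["LL", "T"]) / 2,
              aVL = amps["LA", "T"] - (amps["RA", "T"] + amps["LL", "T"]) / 2,
              aVF = amps["LL", "T"] - (amps["RA", "T"] + amps["LA", "T"]) / 2,
              amps[c("V1", "V2", "V3", "V4", "V5", "V6"), "T"])
  qrs <- rel >= -0.060 & rel <= 0.080
  pw  <- rel >= -0.250 & rel <= -0.100
  out <- t(sapply(LEAD_NAMES, function(nm) {
    v <- leads[, nm]
    r <- max(v[qrs]); s <- min(v[qrs])
    c(P = max(abs(v[pw])), R = abs(r), RS = r - s, T = abs(lead_t[[nm]]))
  }))
  out
}

#' Simulate a cohort of subjects with ECGs, phenotypes and a latent group
#'
#' Each subject belongs to one of two equally sized latent "tender
#' emotionality" groups. The high group's T-wave amplitudes are scaled up by
#' `1 + group_contrast / 2` and the low group's down by `1 - group_contrast
#' / 2`, which drives the downstream Ekappa score apart between groups
#' (Ekappa rises with T_aVL). Six NEO scores are standard-normal scales
#' linearly coupled to the latent group (neuroticism negatively, the other
#' five positively).
#'
#' @param n even number of subjects (>= 4).
#' @param group_contrast relative T-amplitude shift between latent groups;
#'   0 = null cohort.
#' @param seed integer seed.
#' @param neo_coupling correlation-scale coupling of NEO scores to the
#'   latent group (0..1).
#' @param duration_s,sampling_hz,noise_sd_mv passed to the ECG generator.
#' @param heart_rate_range per-subject heart rates drawn uniformly (bpm).
#' @param gain_sd SD of the per-subject log-normal overall gain (cancels in
#'   the Ekappa amplitude ratios).
#' @param wave_jitter_sd SD of per-subject, per-wave-type log-normal gains.
#' @param amp_jitter_sd SD of per-waveform (electrode/chest) log-normal
#'   jitter.
#' @param n_female number of subjects coded gender = 1 (default roughly
#'   half, 12 when `n` is 22 as in the functional cohort).
#' @param age_range years, uniform.
#' @return list with `phenotypes` (data.frame: subject_id, age, gender, six
#'   NEO scores, latent_group), `recordings` (list of `ecg_recording`), and
#'   `params` (per-subject generator parameters).
#' @export
simulate_ecg_cohort <- function(n, group_contrast = 0.6, seed = 1,
                                neo_coupling = 0.5, duration_s = 120,
                                sampling_hz = 1000, noise_sd_mv = 0.01,
                                heart_rate_range = c(55, 70),
                                gain_sd = 0.2, wave_jitter_sd = 0.05,
                                amp_jitter_sd = 0.03, n_female = NULL,
                                age_range = c(19, 31)) {
  stop_if(n < 4, "n must be >= 4")
  stop_if(n %% 2 != 0, "n must be even (balanced latent groups)")
  set.seed(seed)
  if (is.null(n_female)) n_female <- if (n == 22) 12L else floor(n / 2)
  group <- sample(rep(c(-1, 1), each = n / 2))
  gender <- sample(rep(c(1, 0), c(n_female, n - n_female)))
  age <- round(runif(n, age_range[1], age_range[2]))
  neo_names <- c("neuroticism", "extraversion", "agreeableness",
                 "warmth", "positive_emotion", "tender_mindedness")
  dirs <- c(-1, 1, 1, 1, 1, 1)
  neo <- sapply(seq_along(neo_names), function(j)
    dirs[j] * neo_coupling * group +
      sqrt(1 - neo_coupling^2) * rnorm(n))
  colnames(neo) <- neo_names
  base <- .DEFAULT_AMPLITUDES()
  recordings <- vector("list", n)
  par_list <- vector("list", n)
  for (i in seq_len(n)) {
    la <- base
    gain <- exp(rnorm(1, sd = gain_sd))
    wave_gain <- exp(rnorm(4, sd = wave_jitter_sd))
    jit <- function(m) {
      m <- m * exp(matrix(rnorm(length(m), sd = amp_jitter_sd), nrow(m),
                          dimnames = dimnames(m)))
      gain * sweep(m, 2, wave_gain, `*`)
    }
    la$electrodes <- jit(la$electrodes)
    la$chest <- jit(la$chest)
    tf <- 1 + group_contrast / 2 * group[i]
    la$electrodes[, "T"] <- la$electrodes[, "T"] * tf
    la$chest[, "T"] <- la$chest[, "T"] * tf
    p <- ecg_gen_params(
      heart_rate_bpm = runif(1, heart_rate_range[1], heart_rate_range[2]),
      duration_s = duration_s, sampling_hz = sampling_hz,
      lead_amplitudes = la, noise_sd_mv = noise_sd_mv, seed = NULL)
    par_list[[i]] <- p
    recordings[[i]] <- simulate_ecg(p)
  }
  phenotypes <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                           age = age, gender = gender, neo,
                           latent_group = group)
  list(phenotypes = phenotypes, recordings = recordings, params = par_list)
}
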