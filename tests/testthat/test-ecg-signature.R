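test_that("beat detection finds all beats of a clean recording with no flags", {
  fx <- std_ecg()
  expect_length(fx$ann$r_peaks, 120)
  expect_false(any(fx$ann$artifact_flags))
  # detected R peaks within 2 ms of generator truth
  err_ms <- abs((fx$ann$r_peaks - 1) / fx$rec$sampling_hz -
                  attr(fx$rec, "r_times")) * 1000
  expect_lt(max(err_ms), 2)
  expect_error(detect_beats(simulate_ecg(ecg_gen_params(duration_s = 5))),
               "at least 10 s")
})

test_that("an injected motion transient flags exactly that beat", {
  p <- ecg_gen_params(duration_s = 60, artifact_beats = 30L)
  ann <- detect_beats(simulate_ecg(p))
  expect_length(ann$r_peaks, 60)
  expect_equal(which(ann$artifact_flags), 30)
})

test_that("extreme heart rates warn", {
  expect_warning(detect_beats(simulate_ecg(ecg_gen_params(
    heart_rate_bpm = 24, duration_s = 40))), "outside 30-200")
})

test_that("averaging identical noiseless beats reproduces a single beat", {
  fx <- std_ecg()
  fs <- fx$rec$sampling_hz
  r <- fx$ann$r_peaks[60]
  single <- fx$rec$samples[(r - 450):(r + 549), ]
  expect_lt(max(abs(fx$cyc$waveform - single)), 1e-9)
  expect_equal(fx$cyc$n_beats_averaged, 120)
})

test_that("averaging N noisy beats reduces noise like 1/sqrt(N)", {
  sigma <- 0.05
  p0 <- ecg_gen_params(duration_s = 60)
  p1 <- ecg_gen_params(duration_s = 60, noise_sd_mv = sigma, seed = 8)
  rec0 <- simulate_ecg(p0)
  rec1 <- simulate_ecg(p1)
  ann <- detect_beats(rec1, artifact_mad_mult = 6)
  cyc1 <- average_beats(rec1, ann)
  cyc0 <- average_beats(rec0, detect_beats(rec0))
  nbar <- cyc1$n_beats_averaged
  resid_sd <- sd(cyc1$waveform[, "V5"] - cyc0$waveform[, "V5"])
  expect_lt(abs(resid_sd - sigma / sqrt(nbar)) / (sigma / sqrt(nbar)), 0.2)
})

test_that("flagged artifact beats are excluded from the average", {
  p_art <- ecg_gen_params(duration_s = 60, artifact_beats = 20L)
  rec_art <- simulate_ecg(p_art)
  cyc_art <- average_beats(rec_art, detect_beats(rec_art))
  clean <- std_ecg()$cyc
  expect_equal(cyc_art$n_beats_averaged, 59)
  # the multi-mV transient leaves no trace in the average
  expect_lt(max(abs(cyc_art$waveform[, "V1"] - clean$waveform[, "V1"])), 1e-6)
  ann_all_bad <- detect_beats(rec_art)
  ann_all_bad$artifact_flags[] <- TRUE
  expect_error(average_beats(rec_art, ann_all_bad), "all beats flagged")
})

test_that("amplitude measurement recovers constructed waveform arithmetic", {
  # flat zero lead: all four amplitudes zero
  flat <- manual_cycle(function(rel) numeric(length(rel)))
  expect_true(all(measure_amplitudes(flat) == 0))
  # R peak 1.2 mV above a zero PR baseline
  rbeat <- manual_cycle(function(rel) gauss_bump(rel, 0, 0.012, 1.2))
  a <- measure_amplitudes(rbeat)
  expect_equal(unname(a["II", "R"]), 1.2, tolerance = 0.01)
  # ST plateau at 0.1 mV with T peak at 0.4 mV: T measured vs the plateau
  tbeat <- manual_cycle(function(rel) {
    plateau <- 0.1 * (rel >= 0.05 & rel <= 0.32)
    gauss_bump(rel, 0, 0.012, 1.0) + plateau +
      gauss_bump(rel, 0.25, 0.03, 0.3)
  })
  a2 <- measure_amplitudes(tbeat)
  expect_equal(unname(a2["II", "T"]), 0.3, tolerance = 0.02)
})

test_that("measured amplitudes match generator ground truth within 2 percent", {
  fx <- std_ecg()
  a <- measure_amplitudes(fx$cyc)
  rel_err <- abs(a[POSITIVE_LEADS, ] - fx$gt[POSITIVE_LEADS, ]) /
    fx$gt[POSITIVE_LEADS, ]
  expect_lt(max(rel_err), 0.02)
})

test_that("Ekappa inputs take the chest-lead maximum and named leads", {
  amps <- matrix(0.5, 12, 4, dimnames = list(LEAD_NAMES,
                                             c("P", "R", "RS", "T")))
  amps[paste0("V", 1:6), "RS"] <- c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0)
  amps["aVL", c("T", "RS")] <- c(0.2, 0.4)
  amps["III", "R"] <- 0.7
  inp <- assemble_ekappa_inputs(amps)
  expect_equal(inp$RS_Vmax, 3.0)
  expect_equal(inp$T_aVL, 0.2)
  expect_equal(inp$RS_aVL, 0.4)
  expect_equal(inp$R_III, 0.7)
  # permuting chest leads leaves the inputs unchanged
  perm <- amps
  perm[paste0("V", 1:6), ] <- amps[paste0("V", c(3, 1, 6, 2, 5, 4)), ]
  expect_equal(assemble_ekappa_inputs(perm), inp)
  expect_error(assemble_ekappa_inputs(amps[1:10, ]), "missing required leads")
})

test_that("compute_ekappa matches the hand-transcribed equation and is linear in alpha", {
  set.seed(5)
  for (i in 1:3) {
    tuple <- list(T_aVL = runif(1, 0.05, 0.5), RS_aVL = runif(1, 0.1, 1),
                  R_III = runif(1, 0.1, 1.5), RS_Vmax = runif(1, 0.5, 3),
                  alpha = 10)
    by_hand <- 10 * (tuple$T_aVL / tuple$RS_aVL -
                       tuple$R_III / tuple$RS_Vmax)
    expect_equal(compute_ekappa(tuple)$ekappa, by_hand, tolerance = 1e-12)
    t1 <- tuple; t1$alpha <- 1
    expect_identical(compute_ekappa(tuple)$ekappa,
                     10 * compute_ekappa(t1)$ekappa)
  }
  # only the maximal chest RS enters
  amps <- std_ecg()$gt
  inp <- assemble_ekappa_inputs(amps)
  amps2 <- amps
  low <- paste0("V", which.min(amps[paste0("V", 1:6), "RS"]))
  amps2[low, "RS"] <- 0.45 * inp$RS_Vmax   # stays below the max when doubled
  amps2[low, "RS"] <- amps2[low, "RS"] * 2
  stopifnot(max(amps2[paste0("V", 1:6), "RS"]) == inp$RS_Vmax)
  expect_identical(compute_ekappa(assemble_ekappa_inputs(amps2))$ekappa,
                   compute_ekappa(inp)$ekappa)
  bad <- inp; bad$RS_aVL <- 0
  expect_error(compute_ekappa(bad), "denominator")
})

test_that("the pipeline is invariant to recording start phase and sampling rate", {
  fx <- std_ecg()
  ek0 <- compute_ekappa(assemble_ekappa_inputs(
    measure_amplitudes(fx$cyc)))$ekappa
  # start-phase shift: drop the first 0.7 s (less than one cycle)
  shifted <- ecg_recording(fx$rec$samples[-(1:700), ], fx$rec$sampling_hz)
  cyc_s <- average_beats(shifted, detect_beats(shifted))
  ek_s <- compute_ekappa(assemble_ekappa_inputs(
    measure_amplitudes(cyc_s)))$ekappa
  expect_equal(ek_s, ek0, tolerance = 1e-3)
  # halved sampling rate changes Ekappa by < 2 percent
  p500 <- ecg_gen_params(sampling_hz = 500)
  rec500 <- simulate_ecg(p500)
  cyc500 <- average_beats(rec500, detect_beats(rec500))
  ek500 <- compute_ekappa(assemble_ekappa_inputs(
    measure_amplitudes(cyc500)))$ekappa
  expect_lt(abs(ek500 - ek0) / abs(ek0), 0.02)
})
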