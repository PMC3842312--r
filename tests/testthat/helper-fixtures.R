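# Shared fixtures, built once per test session.

# Canonical noiseless 2-min, 60 bpm, 1000 Hz recording and its annotations.
std_ecg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- ecg_gen_params()
      rec <- simulate_ecg(p)
      ann <- suppressWarnings(detect_beats(rec))
      cache <<- list(params = p, rec = rec, ann = ann,
                     cyc = average_beats(rec, ann),
                     gt = ecg_ground_truth(p))
    }
    cache
  }
})

# Leads whose QRS is dominantly positive, where the R/RS measurement
# conventions and the generator ground truth coincide.
POSITIVE_LEADS <- c("I", "II", "III", "aVL", "aVF", "V2", "V3", "V4", "V5", "V6")

# Small random volume series for ECM tests.
small_series <- function(dim3 = c(6, 5, 4), nt = 60, seed = 1, voxel_mm = 3,
                         tr_s = 2) {
  set.seed(seed)
  volume_series(array(rnorm(prod(dim3) * nt), c(dim3, nt)), voxel_mm, tr_s)
}

# Manually built averaged cycle from an analytic waveform (1 kHz, 1 s
# cycle, R at sample 451), for amplitude-measurement oracle tests.
manual_cycle <- function(waveform_fun) {
  rel <- seq(-0.45, 0.549, by = 1e-3)
  w <- waveform_fun(rel)
  wf <- matrix(rep(w, 12), ncol = 12, dimnames = list(NULL, LEAD_NAMES))
  structure(list(waveform = wf, r_index = 451L, sampling_hz = 1000,
                 n_beats_averaged = 1L), class = "averaged_cycle")
}

gauss_bump <- function(t, mu, sigma, amp) amp * exp(-(t - mu)^2 / (2 * sigma^2))
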