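# End-to-end analysis chains over the synthetic cohorts.
#
# Chain 1 (functional): ECG cohort -> Ekappa per subject -> median split ->
# BOLD cohort with the hub coupled to the latent group -> per-subject
# session ECMs -> voxel-wise two-sample z map (age/gender nuisance) ->
# Monte Carlo cluster correction -> is the planted hub region flagged?
#
# Chain 2 (structural): ECG cohort -> Ekappa -> median split -> GM cohort
# with the ROI effect planted in the latent high group -> ROI small-volume
# permutation test controlling age, gender and total brain volume.

#' Run the functional (ECM) analysis chain on synthetic cohorts
#'
#' @param seed integer seed for the whole run.
#' @param n subjects (default 22, split 11/11 by the Ekappa median).
#' @param ecg_duration_s per-subject ECG length used for Ekappa scoring.
#' @param group_contrast ECG T-amplitude contrast between latent groups.
#' @param bold_params a [bold_gen_params()].
#' @param cfg a [preprocess_config()].
#' @param thr optional precomputed [monte_carlo_cluster_threshold()] for
#'   the BOLD mask (computed here when NULL).
#' @param mc_iterations iterations if `thr` is NULL.
#' @return list: `ekappa`, `split`, `split_agreement` (with the latent
#'   group), `stat`, `table`, `hub_recovered` (TRUE when a significant
#'   positive cluster overlaps the planted hub/network region).
#' @export
run_exp1_chain <- function(seed, n = 22, ecg_duration_s = 60,
                           group_contrast = 0.6,
                           bold_params = bold_gen_params(),
                           cfg = preprocess_config(), thr = NULL,
                           mc_iterations = 1000) {
  coh <- simulate_ecg_cohort(n, group_contrast = group_contrast,
                             seed = seed, duration_s = ecg_duration_s)
  ek <- vapply(seq_len(n), function(i)
    ekappa_pipeline(coh$recordings[[i]],
                    subject_id = coh$phenotypes$subject_id[i])$ekappa,
    numeric(1))
  split <- median_split(ek)
  agreement <- mean((split == "high") == (coh$phenotypes$latent_group == 1))
  agreement <- max(agreement, 1 - agreement)

  bold <- simulate_bold_cohort(bold_params, traits = coh$phenotypes$latent_group,
                               seed = seed + 500001L)
  maps <- lapply(bold, session_ecm, cfg = cfg)
  mask <- bold[[1]]$mask
  stat <- voxelwise_two_sample(maps, factor(split, levels = c("high", "low")),
                               mask,
                               nuisance = coh$phenotypes[c("age", "gender")])
  if (is.null(thr))
    thr <- monte_carlo_cluster_threshold(mask, bold_params$voxel_mm,
                                         cfg$smooth_fwhm_mm,
                                         n_iterations = mc_iterations,
                                         seed = seed + 900001L)
  tab <- apply_cluster_threshold(stat, thr)
  planted <- c(attr(bold[[1]], "hub_index"), attr(bold[[1]], "network_index"))
  hub_recovered <- FALSE
  sig_pos <- which(tab$significant & tab$sign > 0)
  if (length(sig_pos)) {
    vox <- cluster_voxels(stat, tab[sig_pos, , drop = FALSE], thr$z_form,
                          thr$connectivity)
    hub_recovered <- any(vapply(vox, function(v) any(v %in% planted),
                                logical(1)))
  }
  list(ekappa = ek, split = split, split_agreement = agreement,
       phenotypes = coh$phenotypes, stat = stat, table = tab, thr = thr,
       hub_recovered = hub_recovered)
}

#' Run the structural (VBM/ROI) analysis chain on synthetic cohorts
#'
#' @param seed integer seed for the whole run.
#' @param n subjects (default 60).
#' @param ecg_duration_s,ecg_sampling_hz ECG scale used for Ekappa scoring.
#' @param group_contrast ECG T-amplitude contrast between latent groups.
#' @param gm_params a [gm_gen_params()] (planted ROI effect).
#' @param n_permutations permutations for the small-volume correction.
#' @return list: `ekappa`, `split`, `split_agreement`, `roi` (the
#'   [roi_small_volume()] result), `uncorrected` (extent-thresholded
#'   table), `covariates`.
#' @export
run_exp2_chain <- function(seed, n = 60, ecg_duration_s = 30,
                           ecg_sampling_hz = 500, group_contrast = 0.6,
                           gm_params = gm_gen_params(),
                           n_permutations = 500) {
  coh <- simulate_ecg_cohort(n, group_contrast = group_contrast,
                             seed = seed, duration_s = ecg_duration_s,
                             sampling_hz = ecg_sampling_hz)
  ek <- vapply(coh$recordings, function(r) ekappa_pipeline(r)$ekappa,
               numeric(1))
  split <- median_split(ek)
  agreement <- mean((split == "high") == (coh$phenotypes$latent_group == 1))
  agreement <- max(agreement, 1 - agreement)

  latent <- factor(ifelse(coh$phenotypes$latent_group == 1, "high", "low"),
                   levels = c("low", "high"))
  gm <- simulate_gm_cohort(gm_params, latent, age = coh$phenotypes$age,
                           gender = coh$phenotypes$gender,
                           seed = seed + 500001L)
  mask <- array(TRUE, gm_params$grid_shape)
  nuis <- gm$covariates[c("age", "gender", "total_volume")]
  roi <- roi_small_volume(gm$maps, factor(split, levels = c("high", "low")),
                          mask, gm_params$roi_mask, nuisance = nuis,
                          n_permutations = n_permutations,
                          seed = seed + 900001L)
  stat <- voxelwise_two_sample(gm$maps, factor(split, levels = c("high", "low")),
                               mask, nuisance = nuis)
  unc <- uncorrected_map(stat, p_voxel = 0.001, extent_voxels = 10)
  list(ekappa = ek, split = split, split_agreement = agreement, roi = roi,
       stat = stat, uncorrected = unc, covariates = gm$covariates)
}
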