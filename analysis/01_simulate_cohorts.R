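#!/usr/bin/env Rscript
# Step 1: generate the two synthetic cohorts.
#
# Functional cohort (n = 22, as in the ECM experiment): 12-lead resting
# ECGs with a latent tender-emotionality group contrast on the T-wave
# amplitudes, NEO scores coupled to the latent group, and BOLD-like 4D
# series whose planted hub network couples to the latent group.
# Structural cohort (n = 60): ECGs and grey-matter maps with a d = 1.2
# ROI effect planted in the latent high group.
#
# ECG CSVs and NIfTI volumes go to scratch/ (regenerated on demand);
# phenotype tables go to results/.

suppressPackageStartupMessages(library(cardiohub))
seed <- 20260924L

dir.create("scratch/exp1_ecg", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/exp1_bold", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/exp2", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("Functional cohort: 22 subjects, 2-min 12-lead ECGs ...")
coh1 <- simulate_ecg_cohort(22, seed = seed)
for (i in seq_len(22))
  write_ecg_csv(coh1$recordings[[i]],
                sprintf("scratch/exp1_ecg/%s.csv",
                        coh1$phenotypes$subject_id[i]))
write_phenotypes(coh1$phenotypes, "results/exp1_phenotypes.tsv")

message("Functional cohort: BOLD-like 4D series (48 trials, TR 2 s) ...")
bp <- bold_gen_params()
bold <- simulate_bold_cohort(bp, traits = coh1$phenotypes$latent_group,
                             seed = seed + 1L)
for (i in seq_len(22)) {
  write_volume(bold[[i]]$data,
               sprintf("scratch/exp1_bold/%s.nii.gz",
                       coh1$phenotypes$subject_id[i]),
               voxel_mm = bp$voxel_mm)
  write.table(data.frame(volume = seq_along(bold[[i]]$condition_labels),
                         condition = bold[[i]]$condition_labels),
              sprintf("scratch/exp1_bold/%s_events.tsv",
                      coh1$phenotypes$subject_id[i]),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
saveRDS(list(params = bp,
             hub_index = attr(bold[[1]], "hub_index"),
             network_index = attr(bold[[1]], "network_index")),
        "scratch/exp1_bold/design.rds")

message("Structural cohort: 60 subjects, ECGs + grey-matter maps ...")
coh2 <- simulate_ecg_cohort(60, seed = seed + 2L, duration_s = 60,
                            sampling_hz = 500)
for (i in seq_len(60))
  write_ecg_csv(coh2$recordings[[i]],
                sprintf("scratch/exp2/%s.csv", coh2$phenotypes$subject_id[i]))
write_phenotypes(coh2$phenotypes, "results/exp2_phenotypes.tsv")

gp <- gm_gen_params()
latent <- factor(ifelse(coh2$phenotypes$latent_group == 1, "high", "low"),
                 levels = c("low", "high"))
gm <- simulate_gm_cohort(gp, latent, age = coh2$phenotypes$age,
                         gender = coh2$phenotypes$gender, seed = seed + 3L)
for (i in seq_len(60))
  write_volume(gm$maps[[i]], sprintf("scratch/exp2/%s_gm.nii.gz",
                                     coh2$phenotypes$subject_id[i]),
               voxel_mm = gp$voxel_mm)
write_volume(gp$roi_mask * 1, "scratch/exp2/roi_mask.nii.gz",
             voxel_mm = gp$voxel_mm)
write.table(gm$covariates, "results/exp2_covariates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

write_provenance("results/01_provenance.json",
                 config = list(n_exp1 = 22, n_exp2 = 60,
                               bold_grid = bp$grid_shape,
                               gm_grid = gp$grid_shape,
                               group_contrast = 0.6, effect_d = gp$effect_d),
                 seed = seed)
message("Cohorts written: results/exp1_phenotypes.tsv, ",
        "results/exp2_phenotypes.tsv, volumes under scratch/.")
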