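# Synthetic registered, modulated grey-matter maps: a shared smooth
# anatomical background, subject noise, a per-subject global volume scale
# with age/gender structure, and a planted ROI intensity effect in one
# group. Stands in for segmented, DARTEL-registered, Jacobian-modulated
# GM maps; born registered, no anatomy implied.

#' Parameters for the synthetic grey-matter map generator
#'
#' @param grid_shape 3D voxel counts (default c(16, 16, 12)).
#' @param voxel_mm voxel edge length, mm (default 1.5).
#' @param roi_mask 3D logical array marking the planted ROI (default: a
#'   3x3x3 block near the grid centre).
#' @param effect_d standardized intensity difference added to ROI voxels of
#'   group "high" (in units of the voxel noise SD).
#' @param noise_sd voxel-wise subject noise SD (default 0.1).
#' @param global_scale_sd SD of the per-subject log-normal global volume
#'   factor (default 0.05).
#' @param age_slope,gender_shift global-volume structure: relative change
#'   per year of age and for gender = 1.
#' @param seed integer seed.
#' @export
gm_gen_params <- function(grid_shape = c(16, 16, 12), voxel_mm = 1.5,
                          roi_mask = NULL, effect_d = 1.2, noise_sd = 0.1,
                          global_scale_sd = 0.05,
                          age_slope = -0.004, gender_shift = -0.03,
                          seed = 1) {
  stop_if(!is.finite(effect_d), "effect_d must be finite")
  if (is.null(roi_mask)) {
    roi_mask <- array(FALSE, grid_shape)
    ctr <- floor(grid_shape / 2)
    roi_mask[ctr[1] + 0:2, ctr[2] + 0:2, ctr[3] + 0:2] <- TRUE
  }
  stop_if(!any(roi_mask), "roi_mask is empty")
  stop_if(!identical(dim(roi_mask), as.integer(grid_shape)) &&
            !identical(dim(roi_mask), grid_shape), "roi_mask outside grid")
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                 roi_mask = roi_mask, effect_d = effect_d,
                 noise_sd = noise_sd, global_scale_sd = global_scale_sd,
                 age_slope = age_slope,
                 gender_shift = gender_shift, seed = seed),
            class = "gm_gen_params")
}

#' Simulate a cohort of grey-matter maps with a planted ROI effect
#'
#' All subjects share a smooth anatomical background; ROI voxels of
#' subjects labelled `"high"` are shifted by `effect_d * noise_sd` before
#' the global scaling; each subject's map is multiplied by a log-normal
#' global factor with age/gender structure. The total-volume covariate is
#' the map sum.
#'
#' @param params a [gm_gen_params()].
#' @param group_labels per-subject labels, factor with levels "low",
#'   "high" (or coercible).
#' @param age,gender optional per-subject covariates; generated if NULL.
#' @param seed integer seed (overrides `params$seed` if given).
#' @return list with `maps` (list of 3D arrays), `covariates` (data.frame:
#'   subject_id, age, gender, group, total_volume), and `params`.
#' @export
simulate_gm_cohort <- function(params, group_labels, age = NULL,
                               gender = NULL, seed = NULL) {
  stopifnot(inherits(params, "gm_gen_params"))
  set.seed(if (is.null(seed)) params$seed else seed)
  n <- length(group_labels)
  group <- factor(group_labels, levels = c("low", "high"))
  stop_if(anyNA(group), "group_labels must be 'low'/'high'")
  gs <- params$grid_shape
  if (is.null(age)) age <- round(runif(n, 20, 31))
  if (is.null(gender)) gender <- rbinom(n, 1, 0.5)
  # shared anatomical background: smoothed noise rescaled to [0.2, 0.8]
  bg <- smooth_volume(array(rnorm(prod(gs)), gs), 3 * params$voxel_mm,
                      params$voxel_mm)
  bg <- 0.2 + 0.6 * (bg - min(bg)) / (max(bg) - min(bg))
  maps <- vector("list", n)
  tv <- numeric(n)
  for (i in seq_len(n)) {
    m <- bg + array(rnorm(prod(gs), sd = params$noise_sd), gs)
    if (group[i] == "high")
      m[params$roi_mask] <- m[params$roi_mask] +
        params$effect_d * params$noise_sd
    scale_i <- exp(rnorm(1, sd = params$global_scale_sd)) *
      (1 + params$age_slope * (age[i] - 25) + params$gender_shift * gender[i])
    m <- m * scale_i
    maps[[i]] <- m
    tv[i] <- sum(m)
  }
  covariates <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                           age = age, gender = gender, group = group,
                           total_volume = tv)
  list(maps = maps, covariates = covariates, params = params)
}
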