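# Synthetic BOLD-like 4D series with the 48-trial, 3-condition epoch
# design: per trial 30 s stimulus, 2 s signal tone, 12 s rating, 4 s rest
# (48 s total; 24 volumes at TR 2 s), 16 trials per category. A planted
# "hub" voxel set shares a latent network time course; a surrounding
# network region couples to the same course with a strength that grows
# with a per-subject trait, so eigenvector centrality of the hub region
# carries the trait. Remaining voxels are white noise plus slow cosine
# drifts that the high-pass filter must remove.

#' Parameters for the synthetic BOLD cohort generator
#'
#' @param grid_shape 3D voxel counts (default c(12, 12, 10)).
#' @param voxel_mm voxel edge length, mm (default 3).
#' @param tr_s repetition time, s (default 2).
#' @param n_trials number of trials (default 48).
#' @param trial_layout named per-trial segment durations in s (stimulus 30,
#'   signal 2, rating 12, rest 4); each must be divisible by `tr_s`.
#' @param conditions stimulus category labels (default joy, fear, neutral).
#' @param trials_per_condition trials per category (default `n_trials /
#'   length(conditions)`, 16 at the default design); must sum to `n_trials`.
#' @param hub_voxels n x 3 matrix of voxel indices forming the hub
#'   (default: a 2x2x2 block at the grid centre).
#' @param network_voxels voxel indices of the trait-coupled surround
#'   (default: the 4x4x4 block around the hub, minus the hub).
#' @param hub_coupling correlation-scale coupling of hub voxels to the
#'   latent course (default 0.8).
#' @param network_base,network_slope the surround couples with strength
#'   `network_base + network_slope * trait` (clamped to [0, 0.95]).
#' @param coupling_jitter_sd per-subject SD of the surround coupling.
#' @param noise_sd voxel noise SD (default 1).
#' @param drift_amp amplitude of the slow drifts (default 1.5).
#' @param seed integer seed.
#' @export
bold_gen_params <- function(grid_shape = c(12, 12, 10), voxel_mm = 3,
                            tr_s = 2, n_trials = 48,
                            trial_layout = c(stimulus = 30, signal = 2,
                                             rating = 12, rest = 4),
                            conditions = c("joy", "fear", "neutral"),
                            trials_per_condition = NULL,
                            hub_voxels = NULL, network_voxels = NULL,
                            hub_coupling = 0.8, network_base = 0.35,
                            network_slope = 0.2, coupling_jitter_sd = 0.05,
                            noise_sd = 1, drift_amp = 1.5, seed = 1) {
  stop_if(any(trial_layout %% tr_s != 0),
          "segment durations must be divisible by tr_s")
  if (is.null(trials_per_condition))
    trials_per_condition <- n_trials / length(conditions)
  stop_if(any(trials_per_condition %% 1 != 0),
          "trials_per_condition must be whole numbers")
  stop_if(sum(rep(trials_per_condition, length.out = length(conditions))) !=
            n_trials, "per-category trial counts must sum to n_trials")
  if (is.null(hub_voxels)) {
    ctr <- floor(grid_shape / 2)
    hub_voxels <- as.matrix(expand.grid(ctr[1] + 0:1, ctr[2] + 0:1,
                                        ctr[3] + 0:1))
  }
  hub_voxels <- as.matrix(hub_voxels)
  stop_if(any(hub_voxels < 1) ||
            any(sweep(hub_voxels, 2, grid_shape, ">") > 0),
          "hub_voxels outside grid")
  if (is.null(network_voxels)) {
    ctr <- floor(grid_shape / 2)
    block <- as.matrix(expand.grid(ctr[1] + (-1):2, ctr[2] + (-1):2,
                                   ctr[3] + (-1):2))
    block <- block[block[, 1] >= 1 & block[, 2] >= 1 & block[, 3] >= 1 &
                     block[, 1] <= grid_shape[1] &
                     block[, 2] <= grid_shape[2] &
                     block[, 3] <= grid_shape[3], , drop = FALSE]
    hub_idx <- ijk_to_index(hub_voxels, grid_shape)
    network_voxels <- block[!(ijk_to_index(block, grid_shape) %in% hub_idx), ,
                            drop = FALSE]
  }
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm, tr_s = tr_s,
                 n_trials = n_trials, trial_layout = trial_layout,
                 conditions = conditions,
                 trials_per_condition = trials_per_condition,
                 hub_voxels = hub_voxels, network_voxels = network_voxels,
                 hub_coupling = hub_coupling, network_base = network_base,
                 network_slope = network_slope,
                 coupling_jitter_sd = coupling_jitter_sd,
                 noise_sd = noise_sd, drift_amp = drift_amp, seed = seed),
            class = "bold_gen_params")
}

# Per-volume condition labels for one pseudorandom trial sequence with no
# more than two consecutive trials of the same category.
.trial_sequence <- function(params) {
  counts <- rep(params$trials_per_condition,
                length.out = length(params$conditions))
  pool <- rep(params$conditions, counts)
  for (try in 1:200) {
    seqc <- sample(pool)
    r <- rle(seqc)
    if (all(r$lengths <= 2)) return(seqc)
  }
  seqc
}

#' Per-volume condition labels implied by the trial layout
#'
#' Stimulus volumes carry the trial's category label; signal, rating and
#' rest volumes carry their segment name. Labels partition the time axis.
#'
#' @param params a [bold_gen_params()].
#' @param trial_conditions character vector of per-trial categories.
#' @return character vector of length `n_trials * trial_s / tr_s`.
#' @export
bold_condition_labels <- function(params, trial_conditions) {
  seg_vols <- params$trial_layout / params$tr_s
  unlist(lapply(trial_conditions, function(cond) {
    labs <- c(cond, names(params$trial_layout)[-1])
    rep(labs, seg_vols)
  }), use.names = FALSE)
}

#' Simulate a cohort of BOLD-like 4D series with a trait-coupled hub
#'
#' @param params a [bold_gen_params()].
#' @param traits per-subject numeric trait values driving the
#'   network-to-hub coupling (e.g. +/-1 latent group codes).
#' @param seed integer seed (overrides `params$seed` if given).
#' @return list of [volume_series()], one per subject, each with condition
#'   labels and a `hub_index`/`network_index` attribute (flat voxel
#'   indices of the planted regions).
#' @export
simulate_bold_cohort <- function(params, traits, seed = NULL) {
  stopifnot(inherits(params, "bold_gen_params"))
  set.seed(if (is.null(seed)) params$seed else seed)
  gs <- params$grid_shape
  nvox <- prod(gs)
  trial_s <- sum(params$trial_layout)
  nt <- params$n_trials * trial_s / params$tr_s
  hub_idx <- ijk_to_index(params$hub_voxels, gs)
  net_idx <- ijk_to_index(params$network_voxels, gs)
  tt <- seq_len(nt)
  out <- vector("list", length(traits))
  for (s in seq_along(traits)) {
    latent <- as.numeric(stats::filter(rnorm(nt), 0.3, method = "recursive"))
    latent <- latent / sd(latent)
    c_net <- min(0.95, max(0, params$network_base +
                             params$network_slope * traits[s] +
                             rnorm(1, sd = params$coupling_jitter_sd)))
    dat <- matrix(rnorm(nvox * nt, sd = params$noise_sd), nvox, nt)
    # slow drifts everywhere (exercises the high-pass filter)
    nd <- 3
    dr <- sapply(seq_len(nd), function(k)
      cos(pi * k * (tt - 0.5) / nt))
    dat <- dat + matrix(rnorm(nvox * nd, sd = params$drift_amp), nvox, nd) %*%
      t(dr)
    dat[hub_idx, ] <- dat[hub_idx, ] +
      params$hub_coupling / sqrt(1 - min(params$hub_coupling, 0.95)^2) *
      rep(latent, each = length(hub_idx)) * params$noise_sd
    dat[net_idx, ] <- dat[net_idx, ] +
      c_net / sqrt(1 - c_net^2) *
      rep(latent, each = length(net_idx)) * params$noise_sd
    labels <- bold_condition_labels(params, .trial_sequence(params))
    out[[s]] <- volume_series(array(dat, c(gs, nt)), params$voxel_mm,
                              params$tr_s, mask = array(TRUE, gs),
                              condition_labels = labels)
    attr(out[[s]], "hub_index") <- hub_idx
    attr(out[[s]], "network_index") <- net_idx
    attr(out[[s]], "network_coupling") <- c_net
  }
  out
}
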