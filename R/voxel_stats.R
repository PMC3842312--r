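# Second-level voxel-wise inference: OLS regressions and group contrasts
# with nuisance covariates (t converted to signed z by quantile matching),
# Monte Carlo cluster-extent/cluster-mass FWE thresholds, uncorrected
# extent-thresholded maps, and permutation-based small-volume correction.

# Coerce per-subject maps (list of 3D arrays / centrality_maps, or an
# n x V matrix) to an n x V matrix of in-mask values.
.maps_to_matrix <- function(maps, mask) {
  if (is.matrix(maps)) {
    stop_if(ncol(maps) != sum(mask), "map matrix does not match the mask")
    return(maps)
  }
  t(vapply(maps, function(m) {
    vol <- if (inherits(m, "centrality_map")) m$values else m
    stop_if(!identical(dim(vol), dim(mask)), "map grid does not match mask")
    vol[mask]
  }, numeric(sum(mask))))
}

.build_design <- function(n, interest, nuisance) {
  stop_if(length(interest) != n, "one interest value per map required")
  x <- cbind(intercept = 1, interest = interest)
  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    stop_if(nrow(nuis) != n, "nuisance rows must match maps")
    x <- cbind(x, nuis)
  }
  stop_if(qr(x)$rank < ncol(x), "design matrix is rank deficient")
  stop_if(n < ncol(x) + 2, "too few subjects for the design")
  x
}

# Vectorised OLS t statistics for the interest column over all voxels.
.ols_t <- function(x, y) {
  xtx_inv <- chol2inv(chol(crossprod(x)))
  betas <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% betas
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  k <- which(colnames(x) == "interest")
  se <- sqrt(pmax(sigma2 * xtx_inv[k, k], .Machine$double.xmin))
  list(t = betas[k, ] / se, beta = betas[k, ], df = df)
}

#' Voxel-wise regression of subject maps on a covariate of interest
#'
#' Ordinary least squares of each voxel's values on an intercept, the
#' regressor of interest and optional nuisance covariates; the interest
#' t statistic is converted to a signed z score by quantile matching
#' through the t distribution with the design's residual df.
#'
#' @param maps list of per-subject 3D arrays (or [centrality_map()]s), or
#'   an n x V matrix of in-mask values.
#' @param interest numeric per-subject regressor of interest.
#' @param mask 3D logical analysis mask.
#' @param nuisance optional per-subject covariates of no interest
#'   (matrix/data.frame, e.g. age, gender, total brain volume).
#' @return a `stat_map`: `z` (signed 3D array, 0 outside mask), `df`,
#'   `mask`, `beta` (in-mask interest slopes).
#' @export
voxelwise_regression <- function(maps, interest, mask, nuisance = NULL) {
  y <- .maps_to_matrix(maps, mask)
  x <- .build_design(nrow(y), interest, nuisance)
  fit <- .ols_t(x, y)
  z <- array(0, dim(mask))
  z[mask] <- t_to_z(fit$t, fit$df)
  structure(list(z = z, df = fit$df, mask = mask, beta = fit$beta),
            class = "stat_map")
}

#' Voxel-wise two-sample comparison of subject maps
#'
#' Equivalent to [voxelwise_regression()] with a group-indicator regressor;
#' positive z marks voxels where the first group is larger.
#'
#' @param maps as in [voxelwise_regression()].
#' @param groups two-level factor (or coercible); the first level is the
#'   positive direction.
#' @inheritParams voxelwise_regression
#' @export
voxelwise_two_sample <- function(maps, groups, mask, nuisance = NULL) {
  g <- as.factor(groups)
  stop_if(nlevels(g) != 2, "groups must have exactly two levels")
  stop_if(any(table(g) < 2), "each group needs at least 2 subjects")
  ind <- as.numeric(g == levels(g)[1])
  voxelwise_regression(maps, ind, mask, nuisance)
}

# One smoothed, in-mask-standardised Gaussian null field.
.null_field <- function(mask, fwhm_mm, voxel_mm) {
  f <- array(rnorm(prod(dim(mask))), dim(mask))
  f <- smooth_volume(f, fwhm_mm, voxel_mm)
  v <- f[mask]
  f[] <- 0
  f[mask] <- (v - mean(v)) / sd(v)
  f
}

# Max cluster size and mass over both signs of a z field.
.max_cluster_stats <- function(z, mask, z_form, connectivity) {
  best <- c(size = 0, mass = 0)
  for (sgn in c(1, -1)) {
    supra <- (sgn * z >= z_form) & mask
    if (!any(supra)) next
    lab <- .label_components_c(as.logical(supra), as.integer(dim(mask)),
                               as.integer(connectivity))
    sizes <- tabulate(lab[lab > 0])
    masses <- vapply(seq_along(sizes),
                     function(l) sum(abs(z[lab == l])), numeric(1))
    best["size"] <- max(best["size"], sizes)
    best["mass"] <- max(best["mass"], masses)
  }
  best
}

# Smallest critical value c with null exceedance P(stat >= c) <= alpha.
.critical_ge <- function(stats, alpha) {
  cand <- sort(unique(stats))
  for (c0 in cand) if (mean(stats >= c0) <= alpha) return(c0)
  max(cand) + 1
}

#' Monte Carlo cluster-extent and cluster-mass FWE thresholds
#'
#' Simulates smooth Gaussian null fields on the mask (white noise smoothed
#' to `fwhm_mm`, standardised to unit in-mask variance), thresholds at
#' `z_form` separately for each sign, and records the per-iteration maximum
#' cluster size and mass (sum of suprathreshold |z|) over both signs.
#' Critical values give familywise error `alpha` under the configured
#' significance rule; for the default disjunctive rule ("either size or
#' mass exceeds its critical value") the two per-criterion levels are
#' calibrated jointly so the disjunction itself has null exceedance
#' <= `alpha`.
#'
#' @param mask 3D logical analysis mask.
#' @param voxel_mm voxel edge length in mm.
#' @param fwhm_mm smoothness of the null fields (the pipeline's applied
#'   smoothing), mm.
#' @param z_form cluster-forming threshold (default 2.326, the one-sided
#'   p = .01 normal quantile).
#' @param alpha familywise error level.
#' @param n_iterations Monte Carlo iterations (>= 200).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param rule `"either"` (default), `"size"` or `"mass"`.
#' @param seed integer seed.
#' @return a `cluster_threshold`: `critical_size` (voxels),
#'   `critical_mass`, plus the simulation settings and per-iteration maxima.
#' @export
monte_carlo_cluster_threshold <- function(mask, voxel_mm, fwhm_mm,
                                          z_form = 2.326, alpha = 0.05,
                                          n_iterations = 1000,
                                          connectivity = 26,
                                          rule = c("either", "size", "mass"),
                                          seed = 1) {
  rule <- match.arg(rule)
  stop_if(z_form <= 0, "z_form must be > 0")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stop_if(n_iterations < 200, "need at least 200 iterations")
  set.seed(seed)
  maxima <- matrix(0, n_iterations, 2,
                   dimnames = list(NULL, c("size", "mass")))
  for (i in seq_len(n_iterations)) {
    z <- .null_field(mask, fwhm_mm, voxel_mm)
    maxima[i, ] <- .max_cluster_stats(z, mask, z_form, connectivity)
  }
  if (rule == "either") {
    # joint calibration: largest per-criterion level whose disjunctive
    # null exceedance stays within alpha
    grid <- seq(alpha, alpha / 5, length.out = 40)
    crit_s <- crit_m <- NULL
    for (a in grid) {
      cs <- .critical_ge(maxima[, "size"], a)
      cm <- .critical_ge(maxima[, "mass"], a)
      if (mean(maxima[, "size"] >= cs | maxima[, "mass"] >= cm) <= alpha) {
        crit_s <- cs; crit_m <- cm
        break
      }
    }
    if (is.null(crit_s)) {
      crit_s <- max(maxima[, "size"]) + 1
      crit_m <- max(maxima[, "mass"]) + 1
    }
  } else if (rule == "size") {
    crit_s <- .critical_ge(maxima[, "size"], alpha)
    crit_m <- Inf
  } else {
    crit_m <- .critical_ge(maxima[, "mass"], alpha)
    crit_s <- Inf
  }
  structure(list(z_form = z_form, alpha = alpha,
                 critical_size = crit_s, critical_mass = crit_m,
                 n_iterations = n_iterations, fwhm_mm = fwhm_mm,
                 voxel_mm = voxel_mm, connectivity = connectivity,
                 rule = rule, seed = seed, null_maxima = maxima),
            class = "cluster_threshold")
}

#' Cluster table of a z map under cluster-level thresholds
#'
#' Connected components of suprathreshold voxels, separately per sign,
#' under the threshold's connectivity; a cluster is significant when its
#' size or mass reaches the corresponding critical value (per the
#' threshold's rule).
#'
#' @param stat a `stat_map`.
#' @param thr a [monte_carlo_cluster_threshold()] result.
#' @return data.frame: label, sign, size, mass, peak_z, peak i/j/k,
#'   significant.
#' @export
apply_cluster_threshold <- function(stat, thr) {
  stopifnot(inherits(stat, "stat_map"), inherits(thr, "cluster_threshold"))
  tab <- .cluster_table(stat, thr$z_form, thr$connectivity)
  sig_s <- tab$size >= thr$critical_size
  sig_m <- tab$mass >= thr$critical_mass
  tab$significant <- switch(thr$rule,
                            either = sig_s | sig_m,
                            size = sig_s,
                            mass = sig_m)
  tab
}

#' Flat voxel indices of each cluster in a cluster table
#'
#' Recomputes the connected components used for `tab` and returns, per
#' table row, the flat indices of that cluster's voxels.
#'
#' @param stat the `stat_map` the table came from.
#' @param tab a cluster table from [apply_cluster_threshold()] or
#'   [uncorrected_map()].
#' @param z_form the cluster-forming threshold used.
#' @param connectivity the connectivity used.
#' @return list of integer vectors, one per table row.
#' @export
cluster_voxels <- function(stat, tab, z_form, connectivity = 26) {
  lapply(seq_len(nrow(tab)), function(r) {
    sgn <- tab$sign[r]
    supra <- (sgn * stat$z >= z_form) & stat$mask
    lab <- .label_components_c(as.logical(supra), as.integer(dim(stat$mask)),
                               as.integer(connectivity))
    pk <- ijk_to_index(as.matrix(tab[r, c("peak_i", "peak_j", "peak_k")]),
                       dim(stat$mask))
    which(lab == lab[pk])
  })
}

.cluster_table <- function(stat, z_form, connectivity) {
  z <- stat$z; mask <- stat$mask
  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- (sgn * z >= z_form) & mask
    if (!any(supra)) next
    lab <- .label_components_c(as.logical(supra), as.integer(dim(mask)),
                               as.integer(connectivity))
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      zz <- z[idx]
      pk <- idx[which.max(abs(zz))]
      ijk <- index_to_ijk(pk, dim(mask))
      rows[[length(rows) + 1]] <- data.frame(
        sign = sgn, size = length(idx), mass = sum(abs(zz)),
        peak_z = zz[which.max(abs(zz))],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
    }
  }
  if (!length(rows))
    return(data.frame(label = integer(0), sign = numeric(0),
                      size = integer(0), mass = numeric(0),
                      peak_z = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      significant = logical(0)))
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$size), , drop = FALSE]
  tab <- cbind(label = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab$significant <- FALSE
  tab
}

#' Uncorrected thresholded cluster table
#'
#' Thresholds |z| at the one-sided `p_voxel` normal quantile (p = .001
#' corresponds to z = 3.0902) and drops clusters smaller than
#' `extent_voxels`.
#'
#' @param stat a `stat_map`.
#' @param p_voxel voxel-level one-sided p threshold.
#' @param extent_voxels minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @return data.frame as in [apply_cluster_threshold()]; `significant`
#'   marks clusters surviving the extent rule.
#' @export
uncorrected_map <- function(stat, p_voxel = 0.001, extent_voxels = 10,
                            connectivity = 26) {
  stop_if(p_voxel <= 0 || p_voxel >= 1, "p_voxel must be in (0, 1)")
  z_thr <- qnorm(1 - p_voxel)
  tab <- .cluster_table(stat, z_thr, connectivity)
  tab <- tab[tab$size >= extent_voxels, , drop = FALSE]
  if (nrow(tab)) tab$label <- seq_len(nrow(tab))
  tab$significant <- rep(TRUE, nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Region-of-interest small-volume correction by residual permutation
#'
#' Max-statistic permutation test restricted to the ROI: the reduced
#' (nuisance-only) model is fitted, its residuals are row-permuted and
#' added back to the reduced fit (Freedman-Lane), and the full-model |z|
#' maximum and maximal cluster size/mass over the ROI are recorded per
#' permutation. Peak-level FWE p is the rank of the observed max |z| in
#' the permutation distribution; cluster-level p analogous with `z_form`
#' forming.
#'
#' @param maps,mask as in [voxelwise_regression()].
#' @param interest per-subject regressor (numeric, or a two-level factor
#'   for a group contrast).
#' @param roi 3D logical ROI mask, inside `mask`.
#' @param nuisance optional covariates of no interest (held fixed).
#' @param alpha FWE level.
#' @param n_permutations at least 500.
#' @param z_form cluster-forming threshold inside the ROI.
#' @param connectivity 6, 18 or 26.
#' @param seed integer seed.
#' @return list: `p_peak`, `p_cluster_size`, `p_cluster_mass`,
#'   `peak_abs_z`, `observed` cluster stats, `significant` (peak or
#'   cluster p < alpha), `alpha`.
#' @export
roi_small_volume <- function(maps, interest, mask, roi, nuisance = NULL,
                             alpha = 0.05, n_permutations = 1000,
                             z_form = 2.326, connectivity = 26, seed = 1) {
  stop_if(!any(roi), "ROI is empty")
  stop_if(any(roi & !mask), "ROI must lie within the analysis mask")
  stop_if(n_permutations < 500, "need at least 500 permutations")
  if (is.factor(interest) || is.character(interest)) {
    g <- as.factor(interest)
    stop_if(nlevels(g) != 2, "interest factor must have two levels")
    interest <- as.numeric(g == levels(g)[1])
  }
  y_all <- .maps_to_matrix(maps, mask)
  y <- y_all[, roi[mask], drop = FALSE]
  n <- nrow(y)
  x <- .build_design(n, interest, nuisance)
  zred <- x[, colnames(x) != "interest", drop = FALSE]
  hz <- zred %*% chol2inv(chol(crossprod(zred))) %*% t(zred)
  fitted <- hz %*% y
  resid <- y - fitted

  roi_stats <- function(yy) {
    fit <- .ols_t(x, yy)
    z <- t_to_z(fit$t, fit$df)
    zvol <- array(0, dim(roi))
    zvol[roi] <- z
    cl <- .max_cluster_stats(zvol, roi, z_form, connectivity)
    c(peak = max(abs(z)), cl)
  }
  obs <- roi_stats(y)
  set.seed(seed)
  perm <- matrix(0, n_permutations, 3,
                 dimnames = list(NULL, c("peak", "size", "mass")))
  for (p in seq_len(n_permutations))
    perm[p, ] <- roi_stats(fitted + resid[sample.int(n), , drop = FALSE])
  pval <- function(col) (1 + sum(perm[, col] >= obs[[col]])) /
    (n_permutations + 1)
  res <- list(p_peak = pval("peak"), p_cluster_size = pval("size"),
              p_cluster_mass = pval("mass"), peak_abs_z = obs[["peak"]],
              observed = obs, alpha = alpha,
              n_permutations = n_permutations)
  res$significant <- res$p_peak < alpha ||
    (obs[["size"]] > 0 && res$p_cluster_size < alpha)
  res
}
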