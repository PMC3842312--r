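# Internal helpers shared across modules.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Gaussian kernel sigma for a given full width at half maximum
#' @param fwhm full width at half maximum, in mm
#' @return standard deviation in mm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# 1D Gaussian kernel sampled at voxel centres, truncated at 4 sigma,
# normalised to unit sum. Returns 1 when the kernel is degenerate.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  hw <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Flat index <-> ijk (1-based) for a 3D grid
ijk_to_index <- function(ijk, dim) {
  as.integer((ijk[, 3] - 1) * dim[1] * dim[2] + (ijk[, 2] - 1) * dim[1] + ijk[, 1])
}

index_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  cbind(i = idx0 %% dim[1] + 1L,
        j = (idx0 %/% dim[1]) %% dim[2] + 1L,
        k = idx0 %/% (dim[1] * dim[2]) + 1L)
}

# Signed z score from a t statistic via the t tail probability, stable in the
# far tails through log-scale quantile matching. z(0) = 0 exactly.
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  nz <- t != 0 & is.finite(t)
  lp <- pt(abs(t[nz]), df = df, lower.tail = FALSE, log.p = TRUE)
  z[nz] <- sign(t[nz]) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(t)] <- t[!is.finite(t)]
  z
}
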