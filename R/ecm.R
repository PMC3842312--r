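# Eigenvector centrality mapping of masked 4D series: discrete-cosine
# temporal high-pass filtering, Gaussian spatial smoothing, a nonnegative
# voxel-similarity graph g(r) from pairwise Pearson correlations, and the
# principal eigenvector by (matrix-free) power iteration.

#' Preprocessing configuration for the ECM pipeline
#'
#' @param highpass_cutoff_hz temporal high-pass cutoff in Hz (default 1/90):
#'   discrete-cosine basis functions with frequency below the cutoff (and
#'   the mean) are removed.
#' @param smooth_fwhm_mm isotropic Gaussian spatial smoothing FWHM in mm
#'   (default 6; 0 disables).
#' @export
preprocess_config <- function(highpass_cutoff_hz = 1 / 90,
                              smooth_fwhm_mm = 6) {
  stop_if(highpass_cutoff_hz <= 0, "highpass cutoff must be > 0")
  stop_if(smooth_fwhm_mm < 0, "smoothing FWHM must be >= 0")
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm), class = "preprocess_config")
}

#' Construct a masked 4D volume series
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param tr_s repetition time in seconds.
#' @param mask 3D logical array; inference is restricted to in-mask voxels.
#' @param condition_labels optional per-volume labels (length t).
#' @export
volume_series <- function(data, voxel_mm, tr_s, mask = NULL,
                          condition_labels = NULL) {
  stop_if(length(dim(data)) != 4, "data must be a 4D array")
  d <- dim(data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stop_if(!identical(dim(mask), d[1:3]), "mask does not match the grid")
  stop_if(!any(mask), "mask is empty")
  stop_if(d[4] < 10, "need at least 10 volumes")
  if (!is.null(condition_labels))
    stop_if(length(condition_labels) != d[4],
            "condition_labels must have one entry per volume")
  flat <- matrix(data, prod(d[1:3]), d[4])
  stop_if(any(!is.finite(flat[as.vector(mask), ])),
          "non-finite values inside mask")
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = tr_s, mask = mask,
                 condition_labels = condition_labels),
            class = "volume_series")
}

#' Temporal high-pass filter via discrete-cosine basis projection
#'
#' Removes the voxel-wise mean and every DCT basis function whose frequency
#' `k / (2 * T * TR)` lies below the cutoff; frequencies well above the
#' cutoff pass essentially unchanged.
#'
#' @param series a [volume_series()].
#' @param cfg a [preprocess_config()].
#' @return the filtered [volume_series()].
#' @export
highpass_filter <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "volume_series"))
  d <- dim(series$data)
  nt <- d[4]
  nyq <- 1 / (2 * series$tr_s)
  stop_if(cfg$highpass_cutoff_hz >= nyq,
          sprintf("cutoff %.4g Hz at or above Nyquist %.4g Hz",
                  cfg$highpass_cutoff_hz, nyq))
  k_max <- ceiling(2 * nt * series$tr_s * cfg$highpass_cutoff_hz) - 1
  tt <- seq_len(nt)
  if (k_max >= 1) {
    dct <- sapply(seq_len(k_max), function(k)
      cos(pi * (2 * tt - 1) * k / (2 * nt)))
    basis <- cbind(1, dct)
  } else basis <- matrix(1, nt, 1)
  q <- qr.Q(qr(basis))
  flat <- t(matrix(series$data, prod(d[1:3]), nt))   # T x voxels
  flat <- flat - q %*% crossprod(q, flat)
  out <- series
  out$data <- array(t(flat), d)
  out
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable truncated-Gaussian convolution with `sigma = FWHM /
#' sqrt(8 ln 2)` mm, kernel normalised to unit sum (renormalised at the
#' grid edges, so constant volumes are preserved exactly). Applied per
#' volume for 4D input.
#'
#' @param x 3D or 4D array, or a [volume_series()].
#' @param fwhm_mm smoothing FWHM in mm (ignored for a `volume_series` if
#'   `cfg` is given).
#' @param voxel_mm voxel edge length (taken from the series if given).
#' @param cfg optional [preprocess_config()] supplying the FWHM.
#' @return object of the same shape/class as the input.
#' @export
smooth_volume <- function(x, fwhm_mm = 6, voxel_mm = 1, cfg = NULL) {
  if (inherits(x, "volume_series")) {
    if (!is.null(cfg)) fwhm_mm <- cfg$smooth_fwhm_mm
    out <- x
    out$data <- smooth_volume(x$data, fwhm_mm, x$voxel_mm)
    return(out)
  }
  stop_if(fwhm_mm < 0, "fwhm must be >= 0")
  stop_if(voxel_mm <= 0, "voxel_mm must be > 0")
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  stop_if(is.null(d) || !(length(d) %in% c(3, 4)), "expected a 3D or 4D array")
  k <- gauss_kernel_1d(fwhm_to_sigma(fwhm_mm) / voxel_mm)
  res <- .smooth3d_c(as.numeric(x), as.integer(d[1:3]), k, k, k)
  array(res, d)
}

# Standardise in-mask time series: rows of the returned V x T matrix are
# centred and unit-norm, so tcrossprod gives the correlation matrix.
.standardize_rows <- function(series) {
  d <- dim(series$data)
  y <- matrix(series$data, prod(d[1:3]), d[4])[as.vector(series$mask), ,
                                               drop = FALSE]
  y <- y - rowMeans(y)
  nrm <- sqrt(rowSums(y^2))
  if (any(nrm == 0)) {
    bad <- which(as.vector(series$mask))[which(nrm == 0)[1]]
    ijk <- index_to_ijk(bad, d[1:3])
    stop(sprintf("zero-variance voxel inside mask at (%d, %d, %d)",
                 ijk[1], ijk[2], ijk[3]), call. = FALSE)
  }
  y / nrm
}

#' Dense voxel-similarity matrix
#'
#' Entry (i, j) is `g(r_ij)` of the Pearson correlation of the two in-mask
#' voxels' time series, with `g(r) = (r + 1) / 2` (default, guaranteeing a
#' nonnegative matrix) or `g(r) = max(r, 0)` (`transform = "rectify"`).
#' The diagonal is set to 0.
#'
#' @param x a [volume_series()], or a T x V numeric matrix of time series.
#' @param transform `"shift"` (default) or `"rectify"`.
#' @return symmetric nonnegative V x V matrix with entries in \[0, 1\].
#' @export
similarity_matrix <- function(x, transform = c("shift", "rectify")) {
  transform <- match.arg(transform)
  if (inherits(x, "volume_series")) {
    cmat <- tcrossprod(.standardize_rows(x))
  } else {
    sds <- apply(x, 2, sd)
    stop_if(any(sds == 0),
            sprintf("zero-variance voxel at column %s", which(sds == 0)[1]))
    cmat <- cor(x)
  }
  cmat[cmat > 1] <- 1; cmat[cmat < -1] <- -1
  s <- if (transform == "shift") (cmat + 1) / 2 else pmax(cmat, 0)
  diag(s) <- 0
  s
}

#' Principal eigenvector of a nonnegative similarity by power iteration
#'
#' Starts from the uniform positive vector and iterates
#' `v <- (S + I) v / ||(S + I) v||_2` until the update norm falls below
#' `tol` (default 1e-9) or `max_iter` iterations. The identity shift
#' leaves the principal eigenvector unchanged while guaranteeing
#' convergence on bipartite-like graphs whose extreme eigenvalues have
#' equal magnitude. Accepts a dense similarity matrix or a matrix-free
#' operator (internal `ecm_operator`) so that grids of 1e4+ voxels never
#' form the V x V matrix.
#'
#' @param sim dense nonnegative symmetric matrix, or an operator created by
#'   the ECM pipeline.
#' @param tol convergence tolerance on the Euclidean update norm.
#' @param max_iter iteration cap.
#' @return list with `vector` (nonnegative, unit Euclidean norm),
#'   `iterations`, `lambda` (Rayleigh estimate of the leading eigenvalue).
#' @export
eigenvector_centrality <- function(sim, tol = 1e-9, max_iter = 1000) {
  if (is.matrix(sim)) {
    stop_if(any(sim < 0), "similarity must be nonnegative")
    stop_if(nrow(sim) != ncol(sim), "similarity must be square")
    if (any(rowSums(sim) == 0))
      warning("similarity graph has isolated voxels; may be reducible")
    mult <- function(v) as.numeric(sim %*% v)
    nv <- nrow(sim)
  } else if (inherits(sim, "ecm_operator")) {
    cmat <- sim$c
    nv <- nrow(cmat)
    mult <- function(v) 0.5 * (as.numeric(cmat %*% crossprod(cmat, v)) +
                                 sum(v)) - v
  } else stop("sim must be a matrix or an ecm_operator", call. = FALSE)
  v <- rep(1 / sqrt(nv), nv)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- mult(v)
    lam <- sum(v * w)
    w <- w + v           # identity shift; same eigenvector
    nw <- sqrt(sum(w^2))
    stop_if(nw == 0, "similarity annihilates the start vector")
    w <- w / nw
    delta <- sqrt(sum((w - v)^2))
    v <- w
    if (delta < tol)
      return(list(vector = v, iterations = it, lambda = lam))
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (last delta %.3g, lambda %.6g)",
    max_iter, delta, lam), call. = FALSE)
}

# Matrix-free operator for the default shift transform:
# S v = ((C C' + J) / 2 - I) v with C the standardized V x T data.
.ecm_operator <- function(cmat) structure(list(c = cmat), class = "ecm_operator")

#' Construct a centrality map
#'
#' @param values nonnegative in-mask centrality values (length = number of
#'   in-mask voxels), normalised to unit Euclidean norm.
#' @param mask 3D logical array.
#' @param n_volumes_used number of volumes that entered the similarity.
#' @export
centrality_map <- function(values, mask, n_volumes_used = NA_integer_) {
  stop_if(any(values < 0), "centrality values must be nonnegative")
  nrm <- sqrt(sum(values^2))
  stop_if(abs(nrm - 1) > 1e-9, "centrality values must have unit norm")
  vol <- array(0, dim(mask))
  vol[mask] <- values
  structure(list(values = vol, mask = mask, norm = nrm,
                 n_volumes_used = as.integer(n_volumes_used)),
            class = "centrality_map")
}

#' @export
print.centrality_map <- function(x, ...) {
  cat(sprintf("<centrality_map> %d in-mask voxels, %d volumes, max %.4g\n",
              sum(x$mask), x$n_volumes_used, max(x$values)))
  invisible(x)
}

# Core: centrality of a (sub)set of volumes of a preprocessed series.
.ecm_from_series <- function(series, vols = NULL,
                             transform = "shift", dense = FALSE,
                             tol = 1e-9, max_iter = 1000) {
  sub <- series
  if (!is.null(vols)) {
    sub$data <- series$data[, , , vols, drop = FALSE]
    sub$condition_labels <- NULL
  }
  if (transform == "rectify" || dense) {
    s <- similarity_matrix(sub, transform = transform)
    res <- eigenvector_centrality(s, tol = tol, max_iter = max_iter)
  } else {
    cmat <- .standardize_rows(sub)
    res <- eigenvector_centrality(.ecm_operator(cmat), tol = tol,
                                  max_iter = max_iter)
  }
  centrality_map(abs(res$vector), series$mask,
                 n_volumes_used = dim(sub$data)[4])
}

#' Whole-session eigenvector centrality map
#'
#' High-pass filters, smooths, and computes the centrality of every in-mask
#' voxel treating the whole session as a single trial.
#'
#' @param series a [volume_series()].
#' @param cfg a [preprocess_config()].
#' @param transform similarity transform, see [similarity_matrix()].
#' @param dense force the dense similarity path (testing/oracle use).
#' @return a [centrality_map()].
#' @export
session_ecm <- function(series, cfg = preprocess_config(),
                        transform = c("shift", "rectify"), dense = FALSE) {
  transform <- match.arg(transform)
  pre <- smooth_volume(highpass_filter(series, cfg), cfg = cfg,
                       voxel_mm = series$voxel_mm)
  .ecm_from_series(pre, transform = transform, dense = dense)
}

#' Per-condition averaged eigenvector centrality maps
#'
#' One centrality map per stimulus epoch (consecutive volumes sharing a
#' condition label), then the arithmetic mean of the per-epoch maps within
#' each condition, renormalised to unit Euclidean norm.
#'
#' @param series a [volume_series()] with `condition_labels`.
#' @param cfg a [preprocess_config()].
#' @param conditions labels treated as stimulus conditions.
#' @param min_epoch_volumes minimum volumes per epoch (default 10).
#' @param transform,dense see [session_ecm()].
#' @return named list of [centrality_map()]s, one per condition, each with
#'   an `n_epochs` attribute.
#' @export
condition_ecms <- function(series, cfg = preprocess_config(),
                           conditions = c("joy", "fear", "neutral"),
                           min_epoch_volumes = 10,
                           transform = c("shift", "rectify"), dense = FALSE) {
  transform <- match.arg(transform)
  stop_if(is.null(series$condition_labels), "condition_labels required")
  pre <- smooth_volume(highpass_filter(series, cfg), cfg = cfg,
                       voxel_mm = series$voxel_mm)
  lab <- series$condition_labels
  r <- rle(as.character(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values %in% conditions
  epochs <- data.frame(condition = r$values[keep], start = starts[keep],
                       end = ends[keep])
  short <- epochs$end - epochs$start + 1 < min_epoch_volumes
  stop_if(any(short), sprintf(
    "epoch(s) too short (< %d volumes): %s", min_epoch_volumes,
    paste(which(short), collapse = ", ")))
  out <- list()
  for (cond in unique(epochs$condition)) {
    rows <- which(epochs$condition == cond)
    acc <- NULL
    for (i in rows) {
      m <- .ecm_from_series(pre, vols = epochs$start[i]:epochs$end[i],
                            transform = transform, dense = dense)
      acc <- if (is.null(acc)) m$values else acc + m$values
    }
    avg <- acc[series$mask] / length(rows)
    avg <- avg / sqrt(sum(avg^2))
    cm <- centrality_map(avg, series$mask,
                         n_volumes_used = sum(epochs$end[rows] -
                                                epochs$start[rows] + 1))
    attr(cm, "n_epochs") <- length(rows)
    out[[cond]] <- cm
  }
  out
}
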