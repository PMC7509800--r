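# Voxelwise first-level GLM, percent-signal-change transform, Gaussian
# spatial smoothing, and second-level (one-sample t) group maps.

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian filter with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis (in voxel units); kernels are truncated at 4 sigma and renormalized
#' row-wise at the volume boundary, so constant volumes are preserved
#' exactly. `fwhm_mm = 0` is the identity. 4D inputs are smoothed volume by
#' volume over the three spatial axes.
#'
#' @param vol 3D or 4D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (>= 0; default 12).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 3).
#' @return Smoothed array, same shape as `vol`.
#' @export
smooth_volume <- function(vol, fwhm_mm = 12, voxel_size_mm = 3) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop_config("fwhm_mm must be a single number >= 0")
  }
  if (fwhm_mm == 0) return(vol)
  assert_scalar_number(voxel_size_mm, "voxel_size_mm", positive = TRUE)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  radius <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)

  # boundary-renormalized band matrix for one axis of length n
  conv_mat <- function(n) {
    M <- matrix(0, n, n)
    for (off in -radius:radius) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      M[cbind(i[ok], j[ok])] <- k[off + radius + 1L]
    }
    M / rowSums(M)
  }

  d <- dim(vol)
  if (!length(d) %in% c(3L, 4L)) {
    stop_config("smooth_volume expects a 3D or 4D array")
  }
  # apply the banded smoother along each spatial axis; any 4th (time) axis
  # rides along in the flattened remainder, so 4D data needs no volume loop
  nd <- length(d)
  a <- vol
  for (ax in 1:3) {
    M <- conv_mat(d[ax])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    ap <- aperm(a, perm)
    ap <- array(M %*% matrix(ap, nrow = d[ax]), dim = d[perm])
    a <- aperm(ap, order(perm))
  }
  a
}

#' Fit the voxelwise first-level GLM
#'
#' Ordinary least squares per in-mask voxel against the full design matrix
#' (task regressors + discrete-cosine high-pass basis + intercept). Betas
#' are kept for the task regressors; the high-pass basis and intercept are
#' nuisance. No prewhitening is applied. Because task columns are unit-peak,
#' a beta is the peak response amplitude in signal units.
#'
#' @param session A `bold_session`.
#' @param dm A `design_matrix` with `n_timepoints` matching the session.
#' @param psc Also populate percent signal change via [beta_to_psc()]
#'   (default TRUE).
#' @return An `activation_map`: lists `beta` (and `psc`) of 3D arrays per
#'   task regressor (NA outside the mask), `residual_variance`, `df_resid`,
#'   `baseline` (voxel temporal mean), `mask`, `dim`.
#' @export
fit_glm <- function(session, dm, psc = TRUE) {
  stopifnot(inherits(session, "bold_session"), inherits(dm, "design_matrix"))
  d <- dim(session$data)
  if (d[4] != dm$n_timepoints) {
    stop_config("design has %d timepoints but session has %d",
                dm$n_timepoints, d[4])
  }
  X <- dm$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_config("design matrix is rank deficient: collinear column(s) %s",
                paste(bad, collapse = ", "))
  }

  vox <- which(session$mask)
  Y <- matrix(aperm(session$data, c(4, 1, 2, 3)), nrow = d[4])[, vox, drop = FALSE]
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  df_resid <- nrow(X) - ncol(X)
  rv <- colSums(res^2) / df_resid

  as_vol <- function(values) {
    a <- array(NA_real_, d[1:3])
    a[vox] <- values
    a
  }
  beta <- lapply(dm$task_cols, function(cn) as_vol(B[cn, ]))
  names(beta) <- dm$task_cols

  map <- structure(list(
    beta = beta, psc = NULL,
    residual_variance = as_vol(rv),
    df_resid = df_resid,
    baseline = as_vol(colMeans(Y)),
    mask = session$mask, dim = d[1:3]
  ), class = "activation_map")
  if (psc) map <- beta_to_psc(map, session) else map
}

#' Transform betas to percent signal change
#'
#' `psc = 100 * beta / voxel temporal mean`. Valid because the task
#' regressors are scaled to unit peak, so the beta is the peak-evoked signal
#' excursion in raw units. Voxels with non-positive baseline inside the mask
#' are excluded (set `NA`) and reported with a warning.
#'
#' @param map An `activation_map` from [fit_glm()].
#' @param session The corresponding `bold_session` (used only if the map
#'   lacks a stored baseline).
#' @return The map with `psc` populated.
#' @export
beta_to_psc <- function(map, session = NULL) {
  stopifnot(inherits(map, "activation_map"))
  base <- map$baseline
  if (is.null(base)) {
    stopifnot(inherits(session, "bold_session"))
    base <- apply(session$data, 1:3, mean)
    base[!map$mask] <- NA_real_
  }
  bad <- which(map$mask & !is.na(base) & base <= 0)
  if (length(bad)) {
    warning(sprintf("%d in-mask voxel(s) with non-positive baseline excluded from PSC",
                    length(bad)), call. = FALSE)
    base[bad] <- NA_real_
  }
  map$psc <- lapply(map$beta, function(b) 100 * b / base)
  map
}

#' Second-level voxelwise group map
#'
#' One-sample t test of per-subject percent signal change against zero at
#' every in-mask voxel: `t = mean / SEM`, two-sided p with `n - 1` degrees
#' of freedom. Where the SEM is zero the t value is reported as a signed
#' infinity sentinel (p = 0) for a nonzero mean, and 0 (p = 1) for an
#' all-zero voxel.
#'
#' @param maps List of `activation_map`s with identical geometry (>= 2).
#' @param regressor Task regressor name (default "CUE").
#' @return A `group_map`: `mean_psc`, `sem`, `t`, `p` 3D arrays and
#'   `n_subjects`.
#' @export
group_map <- function(maps, regressor = "CUE") {
  if (length(maps) < 2L) stop_config("group map needs at least 2 subjects")
  dims <- lapply(maps, function(m) m$dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_config("activation maps have mismatched geometry")
  }
  arr <- vapply(maps, function(m) {
    if (is.null(m$psc)) stop_config("activation map lacks psc; run beta_to_psc()")
    m$psc[[regressor]]
  }, array(0, dims[[1]]))
  n <- length(maps)
  mean_psc <- apply(arr, 1:3, mean)
  sdv <- apply(arr, 1:3, stats::sd)
  sem <- sdv / sqrt(n)
  t <- mean_psc / sem
  zero_sem <- !is.na(sem) & sem == 0
  t[zero_sem] <- sign(mean_psc[zero_sem]) * Inf
  t[zero_sem & mean_psc == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[zero_sem & mean_psc != 0] <- 0
  p[zero_sem & mean_psc == 0] <- 1
  structure(list(mean_psc = mean_psc, sem = sem, t = t, p = p,
                 n_subjects = n, regressor = regressor),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  tv <- x$t[is.finite(x$t)]
  cat(sprintf("group_map (%s, n = %d): t range [%.2f, %.2f], %d voxels with |t| >= 4\n",
              x$regressor, x$n_subjects,
              if (length(tv)) min(tv) else NA, if (length(tv)) max(tv) else NA,
              sum(abs(x$t) >= 4, na.rm = TRUE)))
  invisible(x)
}

#' Threshold a group map for display overlays
#'
#' Returns a copy of the t map with sub-threshold voxels zeroed, mirroring
#' the customary symmetric display (|T| >= 4: positive = activation,
#' negative = deactivation).
#'
#' @param group A `group_map`.
#' @param t_threshold Display threshold (default 4).
#' @return 3D array of thresholded t values.
#' @export
threshold_map <- function(group, t_threshold = 4) {
  out <- group$t
  out[is.na(out) | abs(out) < t_threshold] <- 0
  out
}
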