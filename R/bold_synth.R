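# Synthetic-data generator: per-subject 4D BOLD sessions with planted
# network effects (task-positive CEN seeds, task-negative DMN seeds),
# AR(1) temporal noise, low-frequency drift, a cohort-level rank-correlation
# coupling between DMN response amplitude and MFI-total, ellipsoidal tumor
# masks, and behavior logs. All generators are pure functions of
# (configuration, seed).

BASELINE_SIGNAL <- 1000  # arbitrary units; makes percent-signal-change legible

#' Synthetic scan geometry
#'
#' A reduced-extent box "brain" with isotropic voxels and an axis-aligned
#' affine centered on the origin, so that x = 0 falls on a cube boundary of
#' the default ROI grid and the grid is mirror-symmetric.
#'
#' @param dim 3-vector of voxel counts (default `c(20, 20, 20)`, i.e. a
#'   60 mm box at 3 mm voxels).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 3).
#' @return A `bold_geometry`: `dim`, `voxel_size_mm`, `affine`, `mask`
#'   (all-TRUE box mask).
#' @export
bold_geometry <- function(dim = c(20L, 20L, 20L), voxel_size_mm = 3) {
  stopifnot(length(dim) == 3L, all(dim >= 1))
  assert_scalar_number(voxel_size_mm, "voxel_size_mm", positive = TRUE)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  # voxel (0,0,0) center at -extent/2 + half a voxel: box centered on origin
  affine[1:3, 4] <- -voxel_size_mm * dim / 2 + voxel_size_mm / 2
  structure(list(dim = as.integer(dim), voxel_size_mm = voxel_size_mm,
                 affine = affine, mask = array(TRUE, dim)),
            class = "bold_geometry")
}

#' Cohort generation parameters
#'
#' Defaults emulate the statistical structure of the study population the
#' pipeline targets: 63 subjects in three tumor groups (23 meningioma, 21
#' low-grade glioma, 19 high-grade glioma), a planted Spearman correlation
#' of 0.47 between the DMN response amplitude and MFI-total, CEN amplitudes
#' independent of fatigue, mean planted amplitudes at the observed network
#' scale (+0.10% CEN, -0.10% DMN of baseline) with a between-subject SD of
#' 0.08% (SEM 0.01% at n = 63).
#'
#' @param n_subjects Cohort size (>= 3; default 63).
#' @param planted_rho Target Spearman correlation between DMN amplitude and
#'   MFI-total, in [-1, 1] (default 0.47).
#' @param cen_rho Same for CEN amplitude (default 0: independent).
#' @param cen_amplitude_pct Mean planted CUE response in CEN seed voxels, %
#'   of baseline (default 0.10).
#' @param dmn_amplitude_pct Mean planted CUE response in DMN seed voxels
#'   (default -0.10).
#' @param amplitude_sd_pct Between-subject SD of the planted amplitudes
#'   (default 0.08).
#' @param noise_sd_pct Stationary SD of the AR(1) voxel noise, % of baseline
#'   (default 1).
#' @param ar1_coef Lag-1 autocorrelation of the voxel noise, in [0, 1)
#'   (default 0.3).
#' @param drift_amplitude_pct Amplitude of the low-frequency cosine drift
#'   (default 0.5).
#' @param drift_period_s Drift period in seconds; slower than the 128 s
#'   high-pass cutoff so the GLM basis can absorb it (default 300).
#' @param mfi_mean,mfi_sd Mean and SD of the latent MFI-total distribution
#'   before rounding to the 20..100 integer scale (defaults 55, 15).
#' @param accuracy_target,rt_mean_ms,rt_sd_ms Behavior-log parameters
#'   (defaults 0.969, 900 ms, 190 ms).
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 63L, planted_rho = 0.47, cen_rho = 0,
                        cen_amplitude_pct = 0.10, dmn_amplitude_pct = -0.10,
                        amplitude_sd_pct = 0.08,
                        noise_sd_pct = 1, ar1_coef = 0.3,
                        drift_amplitude_pct = 0.5, drift_period_s = 300,
                        mfi_mean = 55, mfi_sd = 15,
                        accuracy_target = 0.969, rt_mean_ms = 900,
                        rt_sd_ms = 190, seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 3L)
  if (abs(planted_rho) > 1 || abs(cen_rho) > 1) {
    stop_config("planted rank correlations must lie in [-1, 1]")
  }
  if (abs(planted_rho) == 1 || abs(cen_rho) == 1) {
    warning("with |planted_rho| = 1 the achievable rank correlation is bounded by MFI ties",
            call. = FALSE)
  }
  assert_scalar_number(noise_sd_pct, "noise_sd_pct", nonneg = TRUE)
  if (!is.numeric(ar1_coef) || ar1_coef < 0 || ar1_coef >= 1) {
    stop_config("ar1_coef must lie in [0, 1)")
  }
  assert_scalar_number(drift_amplitude_pct, "drift_amplitude_pct", nonneg = TRUE)
  if (accuracy_target < 0 || accuracy_target > 1) {
    stop_config("accuracy_target must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# Pearson parameter of the Gaussian copula that makes the *expected sample*
# Spearman correlation at sample size n equal rho_s. Uses the exact
# bivariate-normal expectation E[r_s] = 6/(pi (n+1)) [asin(r) + (n-2) asin(r/2)]
# (which tends to the familiar (6/pi) asin(r/2) as n grows) and inverts it
# numerically. Without this finite-n calibration the planted correlation
# would be recovered with a systematic ~1% downward bias at n = 63.
copula_pearson <- function(rho_s, n) {
  if (rho_s == 0) return(0)
  if (abs(rho_s) >= 1) return(sign(rho_s))
  expected_rs <- function(r) 6 / (pi * (n + 1)) * (asin(r) + (n - 2) * asin(r / 2))
  if (abs(rho_s) >= expected_rs(1)) return(sign(rho_s))
  stats::uniroot(function(r) expected_rs(r) - rho_s,
                 interval = sort(c(0, sign(rho_s))), tol = 1e-12,
                 extendInt = "no")$root
}

# Per-voxel planted CUE amplitude (% of baseline) from the grid's network
# labels: CEN seeds positive, DMN seeds negative, background zero.
planted_amplitude_volume <- function(grid, cen_amplitude_pct, dmn_amplitude_pct) {
  amp <- array(0, grid$dim)
  for (id in names(grid$voxels)) {
    nw <- grid$network_of[[id]]
    if (nw == "CEN") amp[grid$voxels[[id]]] <- cen_amplitude_pct
    if (nw == "DMN") amp[grid$voxels[[id]]] <- dmn_amplitude_pct
  }
  amp
}

#' Synthesize one BOLD session
#'
#' Forward model of the GLM assumptions: each voxel time series is
#' `baseline * (1 + amp/100 * x_CUE + amp/100 * x_CUE_STIM + drift + noise)`
#' where `x_*` are the session's unit-peak task regressors, `amp` is the
#' voxel's planted amplitude (positive in CEN seeds, negative in DMN seeds,
#' zero in background), drift is a low-frequency cosine with a seeded random
#' phase, and noise is stationary AR(1) with SD `noise_sd_pct`% of baseline.
#'
#' @param dm A `design_matrix` for the session's task design.
#' @param geometry A `bold_geometry`.
#' @param grid A `roi_grid` over the geometry with network labels marking
#'   seed ROIs (see [set_networks()]).
#' @param cen_amplitude_pct,dmn_amplitude_pct Planted response amplitudes
#'   for this subject, % of baseline.
#' @param noise_sd_pct,ar1_coef,drift_amplitude_pct,drift_period_s Noise and
#'   drift parameters, see [cohort_spec()].
#' @param seed Integer seed.
#' @return A `bold_session`: 4D `data`, `tr_s`, `voxel_size_mm`, `affine`,
#'   `mask`.
#' @export
synthesize_session <- function(dm, geometry, grid,
                               cen_amplitude_pct = 0.10,
                               dmn_amplitude_pct = -0.10,
                               noise_sd_pct = 1, ar1_coef = 0.3,
                               drift_amplitude_pct = 0.5, drift_period_s = 300,
                               seed = 1L) {
  stopifnot(inherits(dm, "design_matrix"), inherits(geometry, "bold_geometry"))
  if (!identical(grid$dim, geometry$dim)) {
    stop_config("grid geometry (%s) does not match session geometry (%s)",
                paste(grid$dim, collapse = "x"), paste(geometry$dim, collapse = "x"))
  }
  d <- geometry$dim
  n_t <- dm$n_timepoints
  n_v <- prod(d)
  amp <- planted_amplitude_volume(grid, cen_amplitude_pct, dmn_amplitude_pct)

  # The planted regressor is mean-centered so that the planted amplitude is
  # a percentage of the voxel's temporal mean signal (the same baseline the
  # percent-signal-change transform divides by); the centering constant is
  # absorbed by the GLM intercept, so betas are unaffected.
  xt <- dm$X[, "CUE"] + dm$X[, "CUE_STIM"]
  task <- outer(xt - mean(xt), as.vector(amp) / 100)  # n_t x n_v

  sig <- with_seed(seed, {
    s <- 1 + task
    if (drift_amplitude_pct > 0) {
      # voxelwise slow drift: each voxel gets its own phase and a period
      # jittered around drift_period_s (scanner drift varies across space)
      phase <- stats::runif(n_v, 0, 2 * pi)
      period <- drift_period_s * stats::runif(n_v, 0.75, 1.25)
      t_s <- (seq_len(n_t) - 1L) * dm$tr_s
      arg <- 2 * pi * outer(t_s, 1 / period) +
        matrix(phase, n_t, n_v, byrow = TRUE)
      s <- s + (drift_amplitude_pct / 100) * cos(arg)
    }
    if (noise_sd_pct > 0) {
      innov_sd <- (noise_sd_pct / 100) * sqrt(1 - ar1_coef^2)
      eps <- matrix(stats::rnorm(n_t * n_v, sd = innov_sd), n_t, n_v)
      if (ar1_coef > 0) {
        eps[1L, ] <- eps[1L, ] / sqrt(1 - ar1_coef^2)  # stationary start
        for (t in 2:n_t) eps[t, ] <- ar1_coef * eps[t - 1L, ] + eps[t, ]
      }
      s <- s + eps
    }
    s
  })

  data <- array(t(sig * BASELINE_SIGNAL), dim = c(d, n_t))
  structure(list(data = data, tr_s = dm$tr_s,
                 voxel_size_mm = geometry$voxel_size_mm,
                 affine = geometry$affine, mask = geometry$mask),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_session: %dx%dx%d voxels (%g mm) x %d volumes at TR %g s\n",
              d[1], d[2], d[3], x$voxel_size_mm, d[4], x$tr_s))
  invisible(x)
}

#' Synthesize a cohort with planted fatigue-deactivation coupling
#'
#' Per-subject DMN amplitudes and MFI-total scores are drawn from a Gaussian
#' copula whose Pearson parameter `2 sin(pi rho / 6)` targets the requested
#' Spearman `planted_rho`; CEN amplitudes are drawn independently (or with
#' `cen_rho`). MFI-totals are rounded to the integer 20..100 scale and
#' decomposed into 20 item responses that score back exactly. Subjects are
#' assigned to the three tumor groups in the reference 23/21/19 proportions.
#'
#' @param spec A [cohort_spec()].
#' @param dm A `design_matrix` shared by all subjects.
#' @param geometry A `bold_geometry`.
#' @param grid A `roi_grid` with seed-network labels.
#' @param sessions Generate the 4D BOLD sessions (default TRUE; set FALSE
#'   for amplitude/questionnaire-only draws).
#' @param behavior Also generate behavior logs (default FALSE).
#' @param key MFI scoring key.
#' @return A `cohort`: list with `records` (one `subject_record` per
#'   subject: subject_id, group, planted amplitudes, items, scores, seed)
#'   and `sessions` (list of `bold_session` or NULL).
#' @export
synthesize_cohort <- function(spec, dm, geometry, grid, sessions = TRUE,
                              behavior = FALSE, key = mfi_key(),
                              design = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects

  draws <- with_seed(spec$seed, {
    r_dmn <- copula_pearson(spec$planted_rho, n)
    r_cen <- copula_pearson(spec$cen_rho, n)
    z_mfi <- stats::rnorm(n)
    z_dmn <- r_dmn * z_mfi + sqrt(1 - r_dmn^2) * stats::rnorm(n)
    z_cen <- r_cen * z_mfi + sqrt(1 - r_cen^2) * stats::rnorm(n)
    list(
      mfi_total = pmin(100L, pmax(20L, as.integer(round(spec$mfi_mean + spec$mfi_sd * z_mfi)))),
      dmn_amp = spec$dmn_amplitude_pct + spec$amplitude_sd_pct * z_dmn,
      cen_amp = spec$cen_amplitude_pct + spec$amplitude_sd_pct * z_cen,
      subject_seeds = sample.int(.Machine$integer.max, 3L * n)
    )
  })
  # deterministic split in the reference 23/21/19 proportions
  n_mg <- round(23 / 63 * n)
  n_lgg <- round(21 / 63 * n)
  groups <- c(rep("MG", n_mg), rep("LGG", n_lgg),
              rep("HGG", n - n_mg - n_lgg))

  records <- vector("list", n)
  sess <- if (sessions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    items <- decompose_mfi_total(draws$mfi_total[i], key,
                                 seed = draws$subject_seeds[i])
    scores <- score_mfi(items, key)
    stopifnot(scores$mfi_total == draws$mfi_total[i])
    rec <- structure(list(
      subject_id = sprintf("sub-%03d", i),
      group = groups[i],
      cen_amplitude_pct = draws$cen_amp[i],
      dmn_amplitude_pct = draws$dmn_amp[i],
      mfi_items = items,
      mfi_scores = scores,
      behavior = NULL,
      seed = draws$subject_seeds[n + i]
    ), class = "subject_record")
    if (behavior) {
      if (is.null(design)) stop_config("behavior logs need the task design")
      rec$behavior <- synthesize_behavior(
        design, spec$accuracy_target, spec$rt_mean_ms, spec$rt_sd_ms,
        seed = draws$subject_seeds[2L * n + i])
    }
    records[[i]] <- rec
    if (sessions) {
      sess[[i]] <- synthesize_session(
        dm, geometry, grid,
        cen_amplitude_pct = draws$cen_amp[i],
        dmn_amplitude_pct = draws$dmn_amp[i],
        noise_sd_pct = spec$noise_sd_pct, ar1_coef = spec$ar1_coef,
        drift_amplitude_pct = spec$drift_amplitude_pct,
        drift_period_s = spec$drift_period_s,
        seed = rec$seed)
    }
  }
  structure(list(records = records, sessions = sess, spec = spec),
            class = "cohort")
}

#' Simulate an ellipsoidal tumor mask
#'
#' Rasterizes the ellipsoid `sum(((x - center) / radii)^2) <= 1` on the
#' session voxel grid (a voxel is inside when its center is).
#'
#' @param center_mm World coordinates of the tumor center (inside the
#'   volume).
#' @param radii_mm Three positive semi-axes in mm.
#' @param geometry A `bold_geometry` (or `bold_session`).
#' @return A `tumor_mask`: logical `mask` and `volume_cm3`
#'   (`count * voxel volume / 1000`).
#' @export
simulate_tumor_mask <- function(center_mm, radii_mm, geometry) {
  if (inherits(geometry, "bold_session")) {
    geometry <- structure(list(dim = dim(geometry$data)[1:3],
                               voxel_size_mm = geometry$voxel_size_mm,
                               affine = geometry$affine,
                               mask = geometry$mask), class = "bold_geometry")
  }
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L)
  if (any(radii_mm <= 0)) stop_config("tumor radii must be > 0")
  vc <- voxel_centers(array(TRUE, geometry$dim), geometry$affine)
  lo <- apply(vc$centers, 2, min) - geometry$voxel_size_mm / 2
  hi <- apply(vc$centers, 2, max) + geometry$voxel_size_mm / 2
  if (any(center_mm < lo | center_mm > hi)) {
    stop_config("tumor center (%s) lies outside the volume",
                paste(center_mm, collapse = ", "))
  }
  u <- sweep(vc$centers, 2L, center_mm, "-")
  u <- sweep(u, 2L, radii_mm, "/")
  inside <- rowSums(u^2) <= 1
  mask <- array(FALSE, geometry$dim)
  mask[vc$linear[inside]] <- TRUE
  structure(list(mask = mask,
                 volume_cm3 = sum(mask) * geometry$voxel_size_mm^3 / 1000),
            class = "tumor_mask")
}

#' Synthesize a behavior log for the stimulus trials
#'
#' One response per CUE_STIM trial: correctness is Bernoulli with the target
#' accuracy; reaction times are Gaussian truncated to the response window
#' (0, trial end after stimulus onset].
#'
#' @param design A `task_design`.
#' @param accuracy_target Probability of a correct response, in [0, 1].
#' @param rt_mean_ms,rt_sd_ms Reaction-time mean and SD in ms.
#' @param seed Integer seed.
#' @return Data frame: `trial`, `onset`, `correct`, `rt_ms` (one row per
#'   CUE_STIM trial; zero rows, with a warning, when the design has none).
#' @export
synthesize_behavior <- function(design, accuracy_target = 0.969,
                                rt_mean_ms = 900, rt_sd_ms = 190, seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  if (accuracy_target < 0 || accuracy_target > 1) {
    stop_config("accuracy_target must lie in [0, 1]")
  }
  ev <- design$events
  cs <- ev[ev$trial_type == "CUE_STIM", , drop = FALSE]
  if (nrow(cs) == 0L) {
    warning("design has no CUE_STIM trials: behavior log is empty", call. = FALSE)
    return(data.frame(trial = integer(0), onset = numeric(0),
                      correct = logical(0), rt_ms = numeric(0)))
  }
  window_ms <- (design$trial_duration_s - STIM_ONSET_S) * 1000
  with_seed(seed, {
    n <- nrow(cs)
    correct <- stats::runif(n) < accuracy_target
    rt <- stats::rnorm(n, rt_mean_ms, rt_sd_ms)
    for (i in which(rt <= 0 | rt > window_ms)) {
      while (rt[i] <= 0 || rt[i] > window_ms) {
        rt[i] <- stats::rnorm(1, rt_mean_ms, rt_sd_ms)
      }
    }
    data.frame(trial = seq_len(n), onset = cs$onset, correct = correct,
               rt_ms = rt)
  })
}
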