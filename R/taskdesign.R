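# Task-design generation and GLM design-matrix construction for the
# phasic-alertness paradigm: CUE trials (warning cue alone) and CUE_STIM
# trials (cue followed 2 s later by the arrow-judgment stimulus), presented
# in randomized order inside runs that are enveloped by rest blocks.

# Within-trial timing of the paradigm (ms-level constants, not configurable):
# cue at t = 0 s for 1.5 s; stimulus (CUE_STIM only) at t = +2 s for 1.5 s.
CUE_ONSET_S <- 0
CUE_DURATION_S <- 1.5
STIM_ONSET_S <- 2
STIM_DURATION_S <- 1.5

#' Generate a phasic-alertness task design
#'
#' Lays out `n_runs` task runs, each holding a seeded random permutation of
#' `n_cue_per_run` cue-only (CUE) and `n_cuestim_per_run` cue-plus-stimulus
#' (CUE_STIM) trials stacked back-to-back, with `n_runs + 1` rest blocks
#' enveloping the runs (rest, run, rest, ..., run, rest). Run length is
#' derived from the trial counts: `(n_cue_per_run + n_cuestim_per_run) *
#' trial_duration_s` (+ jitter, if any).
#'
#' @param n_runs Number of task runs (>= 1).
#' @param n_cue_per_run CUE trials per run.
#' @param n_cuestim_per_run CUE_STIM trials per run. One of the two trial
#'   counts may be zero, but each run must contain at least one trial.
#' @param trial_duration_s Duration of one trial in seconds (default 4).
#' @param rest_length_s Length of each rest block in seconds (default 20).
#' @param jitter_s Optional constant inter-trial interval appended to every
#'   trial (default 0; the paradigm presents trials back-to-back).
#' @param seed Integer seed fixing the trial permutation.
#' @return A `task_design` object: a list with an `events` data frame
#'   (columns `onset`, `duration`, `trial_type`, `run`) covering trials and
#'   rest blocks, and the design parameters including the derived
#'   `run_length_s` and `session_duration_s`.
#' @examples
#' d <- task_design(n_runs = 4, seed = 1)
#' table(d$events$trial_type)
#' @export
task_design <- function(n_runs = 4, n_cue_per_run = 20, n_cuestim_per_run = 20,
                        trial_duration_s = 4, rest_length_s = 20,
                        jitter_s = 0, seed = 1L) {
  n_runs <- assert_count(n_runs, "n_runs", min = 1L)
  n_cue_per_run <- assert_count(n_cue_per_run, "n_cue_per_run", min = 0L)
  n_cuestim_per_run <- assert_count(n_cuestim_per_run, "n_cuestim_per_run", min = 0L)
  if (n_cue_per_run + n_cuestim_per_run < 1L) {
    stop_config("each run must contain at least one trial")
  }
  assert_scalar_number(trial_duration_s, "trial_duration_s", positive = TRUE)
  assert_scalar_number(rest_length_s, "rest_length_s", positive = TRUE)
  assert_scalar_number(jitter_s, "jitter_s", nonneg = TRUE)
  if (trial_duration_s < STIM_ONSET_S + STIM_DURATION_S && n_cuestim_per_run > 0) {
    stop_config("trial_duration_s (%g) too short for the %g s stimulus sub-onset",
                trial_duration_s, STIM_ONSET_S + STIM_DURATION_S)
  }

  n_trials <- n_cue_per_run + n_cuestim_per_run
  slot_s <- trial_duration_s + jitter_s
  run_length_s <- n_trials * slot_s

  events <- with_seed(seed, {
    rows <- vector("list", 2L * n_runs + 1L)
    t0 <- 0
    k <- 1L
    for (r in seq_len(n_runs)) {
      rows[[k]] <- data.frame(onset = t0, duration = rest_length_s,
                              trial_type = "REST", run = NA_integer_)
      k <- k + 1L
      t0 <- t0 + rest_length_s
      types <- sample(c(rep("CUE", n_cue_per_run),
                        rep("CUE_STIM", n_cuestim_per_run)))
      rows[[k]] <- data.frame(
        onset = t0 + (seq_len(n_trials) - 1L) * slot_s,
        duration = trial_duration_s,
        trial_type = types,
        run = r
      )
      k <- k + 1L
      t0 <- t0 + run_length_s
    }
    rows[[k]] <- data.frame(onset = t0, duration = rest_length_s,
                            trial_type = "REST", run = NA_integer_)
    do.call(rbind, rows)
  })
  rownames(events) <- NULL

  structure(list(
    events = events,
    n_runs = n_runs,
    n_cue_per_run = n_cue_per_run,
    n_cuestim_per_run = n_cuestim_per_run,
    trial_duration_s = trial_duration_s,
    rest_length_s = rest_length_s,
    jitter_s = jitter_s,
    run_length_s = run_length_s,
    session_duration_s = n_runs * run_length_s + (n_runs + 1) * rest_length_s,
    rng_seed = as.integer(seed)
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "task_design: %d runs x (%d CUE + %d CUE_STIM) trials of %g s, %d rest blocks of %g s\n",
    x$n_runs, x$n_cue_per_run, x$n_cuestim_per_run, x$trial_duration_s,
    x$n_runs + 1L, x$rest_length_s))
  cat(sprintf("  session duration: %g s (seed %d)\n",
              x$session_duration_s, x$rng_seed))
  invisible(x)
}

#' Default canonical HRF parameters
#'
#' Double-gamma parameter set: response gamma with delay (shape) 6 and
#' dispersion (scale) 1, undershoot gamma with delay 16 and dispersion 1,
#' response/undershoot ratio 6, evaluated over a 32 s window. These are the
#' conventional defaults of the canonical BOLD model without derivatives.
#'
#' @return Named list of HRF parameters.
#' @export
hrf_parameters <- function() {
  list(response_delay = 6, undershoot_delay = 16,
       response_dispersion = 1, undershoot_dispersion = 1,
       undershoot_ratio = 6, window_s = 32)
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities sampled on a grid of spacing
#' `tr_s / oversampling` over the HRF window, normalized to unit peak.
#'
#' @param tr_s Repetition time in seconds (> 0).
#' @param oversampling Samples per TR (>= 1); the kernel grid spacing is
#'   `tr_s / oversampling`.
#' @param params HRF parameter list, see [hrf_parameters()].
#' @return List with `time` (seconds) and `value` (unit-peak kernel).
#' @export
canonical_hrf <- function(tr_s, oversampling = 16L, params = hrf_parameters()) {
  assert_scalar_number(tr_s, "tr_s", positive = TRUE)
  oversampling <- assert_count(oversampling, "oversampling", min = 1L)
  dt <- tr_s / oversampling
  t <- seq(0, params$window_s, by = dt)
  h <- stats::dgamma(t, shape = params$response_delay,
                     scale = params$response_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay,
                  scale = params$undershoot_dispersion) / params$undershoot_ratio
  h <- h / max(h)
  list(time = t, value = h)
}

# Discrete-cosine high-pass basis of DCT-II type: columns k = 1..order over
# n scans; mutually orthogonal and orthogonal to the constant (k = 0) term.
dct_basis <- function(n, order) {
  if (order < 1L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  i <- 0:(n - 1L)
  B <- vapply(seq_len(order), function(k) {
    sqrt(2 / n) * cos(pi * (2 * i + 1) * k / (2 * n))
  }, numeric(n))
  colnames(B) <- sprintf("hp_%02d", seq_len(order))
  B
}

# Number of DCT columns needed to span all frequencies below 1/cutoff Hz
# for a session of total_s seconds.
dct_order <- function(total_s, cutoff_s) {
  floor(2 * total_s / cutoff_s)
}

#' Build the GLM design matrix for a task design
#'
#' Produces one regressor per trial type: the CUE column is the boxcar of
#' cue presentations in cue-only trials convolved with the canonical HRF;
#' the CUE_STIM column is the boxcar of cue and stimulus presentations in
#' cue-plus-stimulus trials convolved with the same kernel. Convolution is
#' performed on an oversampled grid and decimated at volume acquisition
#' times `0, tr_s, 2 tr_s, ...`. Each task column is rescaled to unit peak,
#' so a GLM beta is directly the response amplitude in signal units. A
#' discrete-cosine high-pass basis covering all frequencies below
#' `1 / highpass_cutoff_s` Hz and an intercept are appended as nuisance
#' columns.
#'
#' @param design A [task_design()] object.
#' @param tr_s Repetition time in seconds (default 2).
#' @param n_timepoints Number of volumes; defaults to
#'   `ceiling(session_duration_s / tr_s)`. Must cover the session.
#' @param highpass_cutoff_s High-pass cutoff in seconds (default 128).
#' @param oversampling HRF convolution oversampling per TR (default 16).
#' @return A `design_matrix` object: list with matrix `X` (named columns
#'   `CUE`, `CUE_STIM`, `hp_*`, `intercept`), `task_cols`, `tr_s`,
#'   `n_timepoints`, `highpass_cutoff_s`, `hrf_params`.
#' @export
design_matrix <- function(design, tr_s = 2, n_timepoints = NULL,
                          highpass_cutoff_s = 128, oversampling = 16L) {
  stopifnot(inherits(design, "task_design"))
  assert_scalar_number(tr_s, "tr_s", positive = TRUE)
  assert_scalar_number(highpass_cutoff_s, "highpass_cutoff_s", positive = TRUE)
  oversampling <- assert_count(oversampling, "oversampling", min = 1L)
  if (is.null(n_timepoints)) {
    n_timepoints <- ceiling(design$session_duration_s / tr_s)
  }
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 2L)
  if (n_timepoints * tr_s < design$session_duration_s) {
    stop_config("scan too short: %d volumes x %g s < session duration %g s",
                n_timepoints, tr_s, design$session_duration_s)
  }

  params <- hrf_parameters()
  hrf <- canonical_hrf(tr_s, oversampling, params)
  dt <- tr_s / oversampling
  n_fine <- n_timepoints * oversampling
  t_fine <- (0:(n_fine - 1L)) * dt

  boxcar <- function(onsets, durations) {
    b <- numeric(n_fine)
    for (i in seq_along(onsets)) {
      lo <- onsets[i]
      hi <- onsets[i] + durations[i]
      b[t_fine >= lo & t_fine < hi] <- 1
    }
    b
  }
  convolve_hrf <- function(b) {
    if (all(b == 0)) return(numeric(n_timepoints))
    full <- stats::convolve(b, rev(hrf$value), type = "open")[seq_len(n_fine)]
    x <- full[seq(1L, n_fine, by = oversampling)]
    x / max(abs(x))
  }

  ev <- design$events
  cue_trials <- ev[ev$trial_type == "CUE", , drop = FALSE]
  cs_trials <- ev[ev$trial_type == "CUE_STIM", , drop = FALSE]

  x_cue <- convolve_hrf(boxcar(cue_trials$onset + CUE_ONSET_S,
                               rep(CUE_DURATION_S, nrow(cue_trials))))
  x_cs <- convolve_hrf(boxcar(
    c(cs_trials$onset + CUE_ONSET_S, cs_trials$onset + STIM_ONSET_S),
    c(rep(CUE_DURATION_S, nrow(cs_trials)), rep(STIM_DURATION_S, nrow(cs_trials)))
  ))

  hp <- dct_basis(n_timepoints, dct_order(n_timepoints * tr_s, highpass_cutoff_s))
  X <- cbind(CUE = x_cue, CUE_STIM = x_cs, hp, intercept = 1)

  structure(list(
    X = X,
    task_cols = c("CUE", "CUE_STIM"),
    tr_s = tr_s,
    n_timepoints = n_timepoints,
    highpass_cutoff_s = highpass_cutoff_s,
    hrf_params = params
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d volumes at TR %g s, %d columns (%s)\n",
              x$n_timepoints, x$tr_s, ncol(x$X),
              paste(colnames(x$X)[seq_len(min(4, ncol(x$X)))], collapse = ", ")))
  invisible(x)
}

#' Write events to a BIDS-style TSV file
#'
#' Columns: `onset`, `duration`, `trial_type` (CUE, CUE_STIM, REST), `run`.
#'
#' @param design A `task_design` object or an events data frame.
#' @param path Output path.
#' @export
write_events <- function(design, path) {
  ev <- if (inherits(design, "task_design")) design$events else design
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(ev)))
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read events from a BIDS-style TSV file
#'
#' @param path TSV path with columns `onset`, `duration`, `trial_type` and
#'   optionally `run`.
#' @return Events data frame, sorted by onset.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, na.strings = c("n/a", "NA"))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    stop_config("events file %s lacks required columns (%s)", path,
                paste(setdiff(need, names(ev)), collapse = ", "))
  }
  ev[order(ev$onset), , drop = FALSE]
}
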