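# End-to-end analysis: first-level GLMs -> ROI means -> hotspot selection
# and network allocation -> network signals -> brain-behavior inference.

#' Run the full analysis on a cohort
#'
#' For every subject: fit the voxelwise GLM, transform to percent signal
#' change, and average over the grid ROIs. At the group level: build the
#' second-level map for the CUE regressor, select hotspot ROIs (|T| >=
#' `t_threshold` with the mirror rule) and allocate them to CEN/DMN by
#' response sign — or, with `select = FALSE`, reuse the network labels
#' already on the grid. Per-subject network means are then correlated with
#' the MFI scores under the conditional Bonferroni scheme.
#'
#' @param cohort A `cohort` from [synthesize_cohort()] (with sessions), or a
#'   list with `sessions` (list of `bold_session`) and `records` (list with
#'   `subject_id`, `mfi_items`, optionally `group`).
#' @param dm The shared `design_matrix`.
#' @param grid A `roi_grid` over the session geometry.
#' @param t_threshold Hotspot selection threshold (default 4).
#' @param alpha Family-wise level for the two main tests (default 0.05).
#' @param select Use data-driven hotspot selection (default TRUE); when
#'   FALSE the grid's existing `network_of` labels define the networks.
#' @param smooth_fwhm_mm Optional Gaussian smoothing FWHM applied to the 4D
#'   data before the GLM (default 0 = none; the synthetic sessions have no
#'   anatomical misalignment to compensate).
#' @param regressor Task regressor analysed (default "CUE").
#' @param key MFI scoring key.
#' @return List: `report` (`hypothesis_report`), `group` (`group_map`),
#'   `selected`, `network_of`, `signals`, `scores`, `per_roi` (subjects x
#'   ROI matrix), `per_roi_results`, `maps`.
#' @export
analyze_cohort <- function(cohort, dm, grid, t_threshold = 4, alpha = 0.05,
                           select = TRUE, smooth_fwhm_mm = 0,
                           regressor = "CUE", key = mfi_key()) {
  sessions <- cohort$sessions
  records <- cohort$records
  if (is.null(sessions) || !length(sessions)) {
    stop_config("cohort has no sessions to analyze")
  }

  maps <- lapply(sessions, function(s) {
    if (smooth_fwhm_mm > 0) {
      s$data <- smooth_volume(s$data, smooth_fwhm_mm, s$voxel_size_mm)
    }
    fit_glm(s, dm, psc = TRUE)
  })
  group <- group_map(maps, regressor)

  if (select) {
    selected <- select_rois(group, grid, t_threshold = t_threshold)
    if (!length(selected)) {
      stop_config("no ROIs reached |T| >= %g: nothing to analyze", t_threshold)
    }
    network_of <- assign_networks(selected, group, grid)
  } else {
    network_of <- grid$network_of
    selected <- grid$rois$roi_id[network_of != "none"]
    if (!length(selected)) stop_config("grid carries no network labels")
  }

  per_roi <- t(vapply(maps, function(m) roi_mean_psc(m, grid, regressor),
                      numeric(nrow(grid$rois))))
  colnames(per_roi) <- as.character(grid$rois$roi_id)
  per_roi <- per_roi[, as.character(selected), drop = FALSE]

  ids <- vapply(records, function(r) r$subject_id, character(1))
  rownames(per_roi) <- ids
  signals <- data.frame(
    subject_id = ids,
    do.call(rbind, lapply(seq_along(records), function(i) {
      as.data.frame(network_mean(per_roi[i, ], network_of))
    }))
  )
  scores <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, as.data.frame(score_mfi(r$mfi_items, key)))
  }))
  groups <- vapply(records, function(r) r$group %||% NA_character_, character(1))
  groups <- if (all(is.na(groups))) NULL else stats::setNames(groups, ids)

  report <- run_main_hypotheses(signals, scores, alpha = alpha,
                                groups = groups, per_roi = per_roi,
                                network_of = network_of)
  per_roi_results <- per_roi_correlations(per_roi, scores$mfi_total,
                                          network_of, alpha = alpha)

  list(report = report, group = group, selected = selected,
       network_of = network_of, signals = signals, scores = scores,
       per_roi = per_roi, per_roi_results = per_roi_results, maps = maps)
}
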