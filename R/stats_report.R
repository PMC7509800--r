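# Inference layer: Spearman rank correlations between brain signal and
# fatigue scores, the two-main-test Bonferroni scheme with conditional
# follow-up correction, per-ROI exploratory correlations, and report output.

#' Spearman rank correlation with t-approximation p-value
#'
#' Ties are handled by average ranks; rho is the Pearson correlation of the
#' ranks. The two-sided p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` with `df = n - 2`; an optional
#' seeded permutation p-value is available for small samples.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, no missing values.
#' @param role Test role label: "main", "followup" or "posthoc".
#' @param method "t" (default) or "permutation".
#' @param n_perm,perm_seed Permutation count and seed for
#'   `method = "permutation"`.
#' @return A `correlation_result`: `rho`, `n`, `df = n - 2`, `p`, `role`,
#'   `alpha_effective` (NA until set by the correction scheme).
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_cor <- function(x, y, role = "main", method = c("t", "permutation"),
                         n_perm = 10000L, perm_seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_config("missing values are not allowed")
  n <- length(x)
  if (n < 3L) stop_config("need at least 3 observations (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rank correlation undefined", call. = FALSE)
    return(structure(list(rho = NA_real_, n = n, df = n - 2L, p = NA_real_,
                          role = role, alpha_effective = NA_real_),
                     class = "correlation_result"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (method == "t") {
    if (abs(rho) >= 1) {
      0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    with_seed(perm_seed, {
      perm <- replicate(n_perm, abs(stats::cor(x, sample(y), method = "spearman")))
      (1 + sum(perm >= abs(rho))) / (n_perm + 1)
    })
  }
  structure(list(rho = rho, n = n, df = n - 2L, p = p, role = role,
                 alpha_effective = NA_real_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r(%d) = %.3f, p = %.4g [%s]\n", x$df, x$rho, x$p, x$role))
  invisible(x)
}

as_result_row <- function(res, test, network) {
  data.frame(test = test, network = network, rho = res$rho, n = res$n,
             df = res$df, p = res$p, role = res$role,
             alpha_effective = res$alpha_effective,
             significant = !is.na(res$p) & !is.na(res$alpha_effective) &
               res$p < res$alpha_effective)
}

#' Run the two main hypotheses and their conditional follow-ups
#'
#' The two main tests correlate MFI-total with the per-subject mean percent
#' signal change of the CEN and of the DMN; being a family of two, each is
#' judged at `alpha / 2` (Bonferroni). Follow-up analyses per main test are
#' (i) the five MFI domain scores, (ii) MFI-total within each subject group,
#' and (iii) MFI-total per member ROI. When a main test is significant its
#' follow-ups elaborate a significant result and are reported uncorrected at
#' `alpha`; when it is not, its follow-ups are post-hoc and are Bonferroni
#' corrected within that main test's follow-up family.
#'
#' @param signals Data frame with `subject_id`, `cen_psc`, `dmn_psc`.
#' @param scores Data frame with `subject_id`, the five domain scores and
#'   `mfi_total` (see [score_mfi_table()]).
#' @param alpha Family-wise level for the two main tests (default 0.05).
#' @param groups Optional named vector or data frame (`subject_id`,
#'   `group`) for subgroup follow-ups.
#' @param per_roi Optional matrix of per-ROI PSC (rows = subjects in the
#'   same order as `signals`, columns = roi_ids) for per-ROI follow-ups.
#' @param network_of Named character vector roi_id -> network (required with
#'   `per_roi`).
#' @return A `hypothesis_report`: `main` (list CEN/DMN of
#'   `correlation_result`), `results` (tidy data frame of every test),
#'   `alpha`, `correction_note`.
#' @export
run_main_hypotheses <- function(signals, scores, alpha = 0.05, groups = NULL,
                                per_roi = NULL, network_of = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  if (!all(c("subject_id", "cen_psc", "dmn_psc") %in% names(signals))) {
    stop_config("signals must have subject_id, cen_psc, dmn_psc")
  }
  mism <- c(setdiff(signals$subject_id, scores$subject_id),
            setdiff(scores$subject_id, signals$subject_id))
  if (length(mism)) {
    stop_config("signals/scores subject mismatch: %s", paste(mism, collapse = ", "))
  }
  scores <- scores[match(signals$subject_id, scores$subject_id), , drop = FALSE]
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject_id)[signals$subject_id]
  }

  net_col <- c(CEN = "cen_psc", DMN = "dmn_psc")
  main <- lapply(names(net_col), function(nw) {
    res <- spearman_cor(scores$mfi_total, signals[[net_col[nw]]], role = "main")
    res$alpha_effective <- alpha / 2
    res
  })
  names(main) <- names(net_col)

  rows <- list()
  for (nw in names(net_col)) {
    rows[[length(rows) + 1L]] <- as_result_row(main[[nw]], "MFI_total", nw)
  }

  for (nw in names(net_col)) {
    parent_sig <- !is.na(main[[nw]]$p) && main[[nw]]$p < main[[nw]]$alpha_effective
    role <- if (parent_sig) "followup" else "posthoc"
    fam <- list()
    for (d in MFI_DOMAINS) {
      fam[[paste0("domain_", d)]] <-
        spearman_cor(scores[[d]], signals[[net_col[nw]]], role = role)
    }
    if (!is.null(groups)) {
      for (g in unique(groups)) {
        sel <- which(groups == g)
        if (length(sel) >= 3L) {
          fam[[paste0("subgroup_", g)]] <-
            spearman_cor(scores$mfi_total[sel], signals[[net_col[nw]]][sel],
                         role = role)
        }
      }
    }
    if (!is.null(per_roi)) {
      if (is.null(network_of)) stop_config("per_roi follow-ups need network_of")
      ids <- colnames(per_roi)[network_of[colnames(per_roi)] == nw]
      for (id in ids) {
        fam[[paste0("roi_", id)]] <-
          spearman_cor(scores$mfi_total, per_roi[, id], role = role)
      }
    }
    alpha_eff <- if (parent_sig) alpha else alpha / max(1L, length(fam))
    for (nm in names(fam)) {
      fam[[nm]]$alpha_effective <- alpha_eff
      rows[[length(rows) + 1L]] <- as_result_row(fam[[nm]], nm, nw)
    }
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  note <- sprintf(paste0(
    "Two main tests judged at alpha/2 = %.4g (Bonferroni). Follow-ups of a ",
    "significant main test are uncorrected (alpha = %.3g); follow-ups of a ",
    "non-significant main test are post-hoc, Bonferroni-corrected within ",
    "that test's follow-up family."), alpha / 2, alpha)
  structure(list(main = main, results = results, alpha = alpha,
                 correction_note = note),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  for (nw in names(x$main)) {
    m <- x$main[[nw]]
    cat(sprintf("%s vs MFI-total: r(%d) = %.3f, p = %.4g (%ssignificant at %.4g)\n",
                nw, m$df, m$rho, m$p,
                if (!is.na(m$p) && m$p < m$alpha_effective) "" else "not ",
                m$alpha_effective))
  }
  cat(sprintf("%d follow-up tests; %s\n",
              sum(x$results$role != "main"), x$correction_note))
  invisible(x)
}

#' Exploratory per-ROI correlations with MFI-total
#'
#' Correlates MFI-total with the per-subject PSC of every selected ROI and
#' reports the results sorted by correlation strength. Because this
#' exploratory family spans many ROIs, the significance flag uses a
#' Bonferroni threshold of `alpha / n_rois`.
#'
#' @param per_roi Matrix of per-subject ROI PSC (rows = subjects, columns =
#'   roi_ids).
#' @param mfi_total Vector of MFI-total scores, same subject order.
#' @param network_of Named character vector roi_id -> network.
#' @param alpha Nominal level (default 0.05).
#' @return Data frame (roi_id, network, rho, n, df, p, significant), sorted
#'   by |rho| descending.
#' @export
per_roi_correlations <- function(per_roi, mfi_total, network_of, alpha = 0.05) {
  ids <- colnames(per_roi)
  if (is.null(ids)) stop_config("per_roi must have roi_id column names")
  out <- do.call(rbind, lapply(ids, function(id) {
    res <- spearman_cor(mfi_total, per_roi[, id], role = "posthoc")
    nw <- network_of[id]
    data.frame(roi_id = as.integer(id),
               network = if (is.null(nw) || is.na(nw)) "none" else unname(nw),
               rho = res$rho, n = res$n, df = res$df, p = res$p)
  }))
  out$significant <- !is.na(out$p) & out$p < alpha / length(ids)
  out[order(-abs(out$rho)), , drop = FALSE]
}

#' Write the report bundle
#'
#' Writes the pipeline's tabular outputs to `out_dir`: a per-ROI summary
#' (ROI geometry, network, group mean/SEM/T/p, optional tumor overlap), a
#' domain-by-network correlation table, per-subject scatter data (network
#' PSC vs MFI-total), the tidy hypothesis-test table, and a JSON run
#' manifest. Fails (after writing an explanatory stanza) when no ROIs were
#' selected.
#'
#' @param report A `hypothesis_report`.
#' @param group A `group_map`.
#' @param grid A `roi_grid` with network labels.
#' @param signals Per-subject network signal data frame.
#' @param scores Per-subject MFI score data frame.
#' @param out_dir Output directory (created if missing).
#' @param selected Integer vector of selected roi_ids.
#' @param overlap Optional named vector of per-ROI tumor overlap (%).
#' @param manifest Optional named list merged into the run manifest.
#' @return Invisibly, the written paths.
#' @export
build_report <- function(report, group, grid, signals, scores, out_dir,
                         selected = NULL, overlap = NULL, manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(selected)) {
    selected <- grid$rois$roi_id[grid$network_of != "none"]
  }
  if (!length(selected)) {
    writeLines("no ROIs selected: nothing to report",
               file.path(out_dir, "NO_ROIS_SELECTED.txt"))
    stop_config("no ROIs selected")
  }

  r <- grid$rois[match(selected, grid$rois$roi_id), , drop = FALSE]
  roi_t <- vapply(grid$voxels[as.character(selected)],
                  function(v) mean(group$t[v]), numeric(1))
  roi_mean <- vapply(grid$voxels[as.character(selected)],
                     function(v) mean(group$mean_psc[v]), numeric(1))
  roi_sem <- vapply(grid$voxels[as.character(selected)],
                    function(v) mean(group$sem[v]), numeric(1))
  roi_summary <- data.frame(
    roi_id = r$roi_id,
    network = unname(grid$network_of[as.character(r$roi_id)]),
    hemisphere = r$hemisphere,
    center_x = r$center_x, center_y = r$center_y, center_z = r$center_z,
    n_voxels = r$n_voxels,
    mean_psc = roi_mean, sem = roi_sem, t = roi_t,
    p = 2 * stats::pt(-abs(roi_t), df = group$n_subjects - 1)
  )
  if (!is.null(overlap)) {
    roi_summary$tumor_overlap_pct <- unname(overlap[as.character(r$roi_id)])
  }
  p_roi <- file.path(out_dir, "roi_summary.csv")
  utils::write.csv(roi_summary, p_roi, row.names = FALSE)

  res <- report$results
  dom <- res[grepl("^domain_|^MFI_total$", res$test), , drop = FALSE]
  p_dom <- file.path(out_dir, "network_domain_correlations.csv")
  utils::write.csv(dom, p_dom, row.names = FALSE)

  p_tests <- file.path(out_dir, "hypothesis_tests.csv")
  utils::write.csv(res, p_tests, row.names = FALSE)

  scatter <- merge(signals, scores[, c("subject_id", "mfi_total")],
                   by = "subject_id")
  scatter <- scatter[order(scatter$subject_id), , drop = FALSE]
  p_scatter <- file.path(out_dir, "network_scatter.csv")
  utils::write.csv(scatter, p_scatter, row.names = FALSE)

  man <- c(list(package = "phasicfmri",
                version = as.character(utils::packageVersion("phasicfmri")),
                n_subjects = group$n_subjects,
                n_rois_selected = length(selected),
                alpha = report$alpha,
                correction_note = report$correction_note),
           manifest)
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, p_man, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(p_roi, p_dom, p_tests, p_scatter, p_man))
}
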