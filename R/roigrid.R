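# Systematic cubic-grid ROI atlas: the brain mask is partitioned by a fixed
# grid of 15-mm cubes (max 125 voxels of 3 mm per cube), replacing
# data-driven ROI drawing and its risk of circular selection. Includes
# hotspot-based ROI selection with the contralateral mirror rule, allocation
# to the central executive (task-positive) vs default mode (task-negative)
# network, and tumor-overlap statistics.

# World coordinates of in-mask voxel centers. Only shear-free (diagonal
# rotation part) affines are supported; the grid is axis-aligned.
voxel_centers <- function(mask, affine) {
  rot <- affine[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-8)) {
    stop_config("affine has shear/rotation: only axis-aligned grids are supported")
  }
  idx <- which(mask, arr.ind = TRUE) - 1L  # 0-based voxel indices
  centers <- sweep(idx %*% t(rot), 2L, affine[1:3, 4], "+")
  list(linear = which(mask), index = idx, centers = centers)
}

#' Build a systematic cubic ROI grid over a brain mask
#'
#' Every in-mask voxel is assigned to the axis-aligned cube of edge
#' `edge_mm` containing its center (half-open intervals
#' `[corner, corner + edge)`); empty cubes are discarded. Grid planes sit at
#' `origin + k * edge_mm`; the default origin is chosen per axis as the
#' largest grid multiple at or below the minimum voxel center, which places
#' a grid plane at x = 0 and makes the grid mirror-symmetric about the
#' midline. ROIs are numbered by ascending corner z, then y, then x.
#'
#' @param mask 3D logical array (or a `bold_geometry`/`bold_session`, whose
#'   mask and affine are used).
#' @param affine 4x4 voxel-to-world affine (ignored when `mask` carries one).
#' @param edge_mm Cube edge in mm (default 15); must be a positive multiple
#'   of the voxel size.
#' @param origin_mm Optional 3-vector grid anchor in mm; each component must
#'   be a multiple of `edge_mm` so that x = 0 remains a grid plane.
#' @return A `roi_grid` object: `rois` data frame (roi_id, corner/center
#'   coordinates, hemisphere, n_voxels), `voxels` (list of linear voxel
#'   indices per ROI), `network_of` (named character vector, initially
#'   "none"), plus geometry fields.
#' @export
build_roi_grid <- function(mask, affine = NULL, edge_mm = 15, origin_mm = NULL) {
  if (inherits(mask, c("bold_geometry", "bold_session"))) {
    affine <- mask$affine
    mask <- mask$mask
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.matrix(affine))
  if (!any(mask)) stop_config("brain mask is empty")
  assert_scalar_number(edge_mm, "edge_mm", positive = TRUE)
  voxel_size <- abs(diag(affine)[1:3])
  if (any(abs(edge_mm / voxel_size - round(edge_mm / voxel_size)) > 1e-8)) {
    stop_config("edge_mm (%g) must be a multiple of the voxel size (%g)",
                edge_mm, voxel_size[1])
  }

  vc <- voxel_centers(mask, affine)
  if (is.null(origin_mm)) {
    origin_mm <- edge_mm * floor(apply(vc$centers, 2L, min) / edge_mm)
  } else if (any(abs(origin_mm %% edge_mm) > 1e-8 &
                 abs(origin_mm %% edge_mm - edge_mm) > 1e-8)) {
    stop_config("origin_mm components must be multiples of edge_mm so that x = 0 is a grid plane")
  }

  cube <- floor(sweep(vc$centers, 2L, origin_mm, "-") / edge_mm)
  key <- paste(cube[, 1], cube[, 2], cube[, 3], sep = ":")
  groups <- split(seq_along(key), key)
  corners <- do.call(rbind, lapply(groups, function(g) cube[g[1], ] * edge_mm + origin_mm))
  ord <- order(corners[, 3], corners[, 2], corners[, 1])
  groups <- groups[ord]
  corners <- corners[ord, , drop = FALSE]
  centers <- corners + edge_mm / 2

  rois <- data.frame(
    roi_id = seq_along(groups),
    corner_x = corners[, 1], corner_y = corners[, 2], corner_z = corners[, 3],
    center_x = centers[, 1], center_y = centers[, 2], center_z = centers[, 3],
    hemisphere = ifelse(centers[, 1] < 0, "L",
                        ifelse(centers[, 1] > 0, "R", "midline")),
    n_voxels = vapply(groups, length, integer(1))
  )
  rownames(rois) <- NULL
  voxels <- lapply(groups, function(g) vc$linear[g])
  names(voxels) <- as.character(rois$roi_id)
  network_of <- stats::setNames(rep("none", nrow(rois)), as.character(rois$roi_id))

  structure(list(
    rois = rois, voxels = voxels, network_of = network_of,
    edge_mm = edge_mm, origin_mm = origin_mm,
    voxel_size_mm = voxel_size[1], dim = dim(mask), affine = affine
  ), class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("roi_grid: %d cubic ROIs of %g mm (max %d voxels each) over a %s mask\n",
              nrow(x$rois), x$edge_mm, round((x$edge_mm / x$voxel_size_mm)^3),
              paste(x$dim, collapse = "x")))
  if (any(x$network_of != "none")) {
    cat(sprintf("  networks: %d CEN, %d DMN\n",
                sum(x$network_of == "CEN"), sum(x$network_of == "DMN")))
  }
  invisible(x)
}

#' Average a voxel map over each ROI
#'
#' Unweighted mean of the map over every ROI's voxel set.
#'
#' @param vol 3D array (e.g. a percent-signal-change map) matching the grid
#'   geometry, or an `activation_map` with `regressor` naming the map.
#' @param grid A `roi_grid`.
#' @param regressor Regressor name when `vol` is an `activation_map`.
#' @return Named numeric vector, one mean per roi_id.
#' @export
roi_mean_psc <- function(vol, grid, regressor = "CUE") {
  if (inherits(vol, "activation_map")) {
    if (is.null(vol$psc)) stop_config("activation map has no psc; run beta_to_psc() first")
    vol <- vol$psc[[regressor]]
  }
  stopifnot(is.array(vol), identical(dim(vol), grid$dim))
  vapply(grid$voxels, function(v) mean(vol[v]), numeric(1))
}

#' Select activation-hotspot ROIs from a group map
#'
#' An ROI is selected when the absolute value of its ROI-mean group T
#' statistic reaches `t_threshold` (default 4, a reproducible proxy for
#' visual hotspot inspection at the customary display threshold). The
#' contralateral mirror rule is then applied so that unilateral hotspots
#' bring in their opposite-hemisphere counterpart.
#'
#' @param group A `group_map` (computed on the CUE regressor).
#' @param grid A `roi_grid`.
#' @param t_threshold Positive selection threshold on |T| (default 4).
#' @param mirror Apply [apply_mirror_rule()] to the selection (default TRUE).
#' @return Integer vector of selected roi_ids.
#' @export
select_rois <- function(group, grid, t_threshold = 4, mirror = TRUE) {
  if (!(is.numeric(t_threshold) && length(t_threshold) == 1L && t_threshold > 0)) {
    stop_config("t_threshold must be a single positive number")
  }
  tmap <- group$t
  roi_t <- vapply(grid$voxels, function(v) mean(tmap[v]), numeric(1))
  sel <- grid$rois$roi_id[!is.na(roi_t) & abs(roi_t) >= t_threshold]
  if (mirror && length(sel)) sel <- apply_mirror_rule(sel, grid)
  sel
}

#' Add mirror ROIs in the opposite hemisphere
#'
#' For each selected lateralized ROI, the ROI whose center is the reflection
#' `x -> -x` of its center is added when such an ROI exists in the grid.
#' Requires a grid with x = 0 on a grid plane (mirror symmetry); midline
#' ROIs map to themselves and add nothing.
#'
#' @param selected Integer vector of roi_ids.
#' @param grid A `roi_grid`.
#' @return Augmented, sorted, duplicate-free roi_id vector.
#' @export
apply_mirror_rule <- function(selected, grid) {
  if (abs(grid$origin_mm[1] %% grid$edge_mm) > 1e-8 &&
      abs(grid$origin_mm[1] %% grid$edge_mm - grid$edge_mm) > 1e-8) {
    stop_config("grid is not mirror-symmetric: origin x (%g) must be a multiple of edge_mm",
                grid$origin_mm[1])
  }
  r <- grid$rois
  extra <- integer(0)
  for (id in selected) {
    i <- match(id, r$roi_id)
    if (r$center_x[i] == 0) next
    j <- which(abs(r$center_x + r$center_x[i]) < 1e-6 &
                 abs(r$center_y - r$center_y[i]) < 1e-6 &
                 abs(r$center_z - r$center_z[i]) < 1e-6)
    if (length(j)) extra <- c(extra, r$roi_id[j])
  }
  sort(unique(c(selected, extra)))
}

#' Allocate selected ROIs to CEN or DMN by response sign
#'
#' ROIs whose ROI-mean group percent signal change during CUE is positive
#' (activation above the rest baseline) are allocated to the central
#' executive network (CEN); negative means (deactivation) go to the default
#' mode network (DMN); an exact zero is flagged as "none".
#'
#' @param selected Integer vector of selected roi_ids (nonempty).
#' @param group A `group_map` with `mean_psc`.
#' @param grid A `roi_grid`.
#' @return Named character vector over all roi_ids: "CEN", "DMN" or "none".
#' @export
assign_networks <- function(selected, group, grid) {
  if (!length(selected)) stop_config("cannot assign networks to an empty selection")
  roi_mean <- vapply(grid$voxels, function(v) mean(group$mean_psc[v]), numeric(1))
  network_of <- stats::setNames(rep("none", nrow(grid$rois)),
                                as.character(grid$rois$roi_id))
  for (id in selected) {
    m <- roi_mean[as.character(id)]
    network_of[as.character(id)] <- if (m > 0) "CEN" else if (m < 0) "DMN" else "none"
  }
  network_of
}

#' Set network labels on a grid
#'
#' @param grid A `roi_grid`.
#' @param network_of Named character vector roi_id -> network.
#' @return The grid with `network_of` updated.
#' @export
set_networks <- function(grid, network_of) {
  grid$network_of[names(network_of)] <- network_of
  grid
}

#' Per-network mean of per-ROI values
#'
#' Unweighted mean of per-ROI percent signal change over the ROIs of each
#' network, giving the per-subject network signal.
#'
#' @param per_roi_psc Named vector of per-ROI values (names = roi_ids).
#' @param network_of Named character vector roi_id -> {"CEN","DMN","none"}.
#' @return List with `cen_psc` and `dmn_psc` (`NA` with a warning when a
#'   network has no ROI).
#' @export
network_mean <- function(per_roi_psc, network_of) {
  one <- function(nw) {
    ids <- names(network_of)[network_of == nw]
    ids <- intersect(ids, names(per_roi_psc))
    if (!length(ids)) {
      warning(sprintf("network %s has no ROIs: mean undefined", nw), call. = FALSE)
      return(NA_real_)
    }
    mean(per_roi_psc[ids])
  }
  list(cen_psc = one("CEN"), dmn_psc = one("DMN"))
}

#' Tumor overlap of one ROI across a cohort
#'
#' `100 * sum_s |roi voxels in tumor_s| / (n_voxels(roi) * n_subjects)`:
#' the cohort-average percentage of the ROI's voxels that fall inside a
#' subject's tumor.
#'
#' @param masks List of `tumor_mask` objects (or 3D logical arrays), one per
#'   subject, aligned with the grid.
#' @param grid A `roi_grid`.
#' @param roi_id The ROI to evaluate.
#' @return Percentage in 0..100.
#' @export
tumor_overlap_per_roi <- function(masks, grid, roi_id) {
  vox <- grid$voxels[[as.character(roi_id)]]
  if (is.null(vox)) stop_config("unknown roi_id %s", roi_id)
  hits <- vapply(masks, function(m) {
    m <- if (inherits(m, "tumor_mask")) m$mask else m
    if (!identical(dim(m), grid$dim)) stop_config("tumor mask geometry mismatch")
    sum(m[vox])
  }, numeric(1))
  100 * sum(hits) / (length(vox) * length(masks))
}

#' Tumor overlap of one subject across the selected ROIs
#'
#' `100 * sum_roi |roi voxels in tumor| / sum_roi n_voxels(roi)` over the
#' selected ROIs: the percentage of the subject's analysis voxels that fall
#' inside the tumor.
#'
#' @param mask A `tumor_mask` (or 3D logical array) aligned with the grid.
#' @param grid A `roi_grid`.
#' @param selected Integer vector of selected roi_ids (nonempty).
#' @return Percentage in 0..100.
#' @export
tumor_overlap_per_subject <- function(mask, grid, selected) {
  if (!length(selected)) stop_config("tumor overlap undefined for an empty ROI selection")
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  if (!identical(dim(m), grid$dim)) stop_config("tumor mask geometry mismatch")
  vox <- grid$voxels[as.character(selected)]
  hit <- sum(vapply(vox, function(v) sum(m[v]), numeric(1)))
  tot <- sum(vapply(vox, length, integer(1)))
  100 * hit / tot
}

#' Export the grid as a labeled atlas volume and ROI table
#'
#' @param grid A `roi_grid`.
#' @param out_prefix Path prefix; writes `<prefix>_atlas.nii` (voxel value =
#'   roi_id) and `<prefix>_rois.csv`.
#' @return Invisibly, the two paths.
#' @export
write_roi_grid <- function(grid, out_prefix) {
  lab <- array(0L, grid$dim)
  for (id in names(grid$voxels)) lab[grid$voxels[[id]]] <- as.integer(id)
  nii <- paste0(out_prefix, "_atlas.nii")
  write_nifti(lab, nii, affine = grid$affine)
  tab <- grid$rois
  tab$network <- unname(grid$network_of[as.character(tab$roi_id)])
  csv <- paste0(out_prefix, "_rois.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(c(nii, csv))
}
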