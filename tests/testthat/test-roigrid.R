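# brute-force voxel-assignment oracle: independently bin voxel centers
oracle_assignment <- function(mask, affine, edge, origin) {
  idx <- which(mask, arr.ind = TRUE)
  centers <- sweep((idx - 1) %*% diag(diag(affine)[1:3]), 2, affine[1:3, 4], "+")
  cube <- floor(sweep(centers, 2, origin, "-") / edge)
  split(which(mask), paste(cube[, 1], cube[, 2], cube[, 3]))
}

test_that("a grid-aligned 15-mm cube yields one ROI of 125 voxels of 3375 mm^3", {
  geom <- bold_geometry(c(10, 10, 10))
  mask <- array(FALSE, geom$dim)
  mask[1:5, 1:5, 1:5] <- TRUE  # exactly one aligned cube
  grid <- build_roi_grid(mask, geom$affine)
  expect_equal(nrow(grid$rois), 1)
  expect_equal(grid$rois$n_voxels, 125)
  expect_equal(grid$edge_mm^3, 3375)
})

test_that("a 30-mm aligned box partitions into 8 disjoint ROIs matching the oracle", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  expect_equal(nrow(grid$rois), 8)
  expect_true(all(grid$rois$n_voxels == 125))
  all_vox <- sort(unname(unlist(grid$voxels)))
  expect_equal(all_vox, which(geom$mask))          # union = mask
  expect_equal(anyDuplicated(unlist(grid$voxels)), 0)  # disjoint
  oracle <- oracle_assignment(geom$mask, geom$affine, 15, grid$origin_mm)
  canon <- function(groups) sort(vapply(groups, function(v)
    paste(sort(v), collapse = ","), character(1)), method = "radix")
  expect_equal(unname(canon(grid$voxels)), unname(canon(oracle)))
})

test_that("the partition property holds on random masks", {
  geom <- bold_geometry(c(11, 9, 7))
  set.seed(99)
  for (i in 1:50) {
    mask <- array(stats::runif(prod(geom$dim)) < 0.4, geom$dim)
    if (!any(mask)) next
    grid <- build_roi_grid(mask, geom$affine)
    expect_equal(sum(grid$rois$n_voxels), sum(mask))
    expect_equal(sort(unname(unlist(grid$voxels))), which(mask))
  }
})

test_that("grid construction validates geometry", {
  geom <- bold_geometry(c(6, 6, 6))
  expect_error(build_roi_grid(array(FALSE, geom$dim), geom$affine), "empty")
  sheared <- geom$affine
  sheared[1, 2] <- 0.5
  expect_error(build_roi_grid(geom$mask, sheared), "shear")
  expect_error(build_roi_grid(geom$mask, geom$affine, edge_mm = 10), "multiple")
  expect_error(build_roi_grid(geom$mask, geom$affine, origin_mm = c(-7, 0, 0)),
               "multiples")
})

test_that("roi_mean_psc equals the brute-force voxel-averaging oracle", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  vol <- array(stats::rnorm(prod(geom$dim)), geom$dim)
  means <- roi_mean_psc(vol, grid)
  for (id in names(grid$voxels)) {
    expect_lt(abs(means[id] - mean(vol[grid$voxels[[id]]])), 1e-12)
  }
  # constant map -> every ROI mean = c; half +1 / half -1 -> 0
  expect_true(all(abs(roi_mean_psc(array(3.3, geom$dim), grid) - 3.3) < 1e-12))
  half <- array(rep(c(1, -1), length.out = prod(geom$dim)), geom$dim)
  expect_lt(abs(mean(roi_mean_psc(half, grid))), 1e-12)
})

test_that("hotspot selection respects thresholds and endpoints", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  zero_group <- list(t = array(0, geom$dim), mean_psc = array(0, geom$dim))
  expect_length(select_rois(zero_group, grid), 0)
  big <- list(t = array(10, geom$dim), mean_psc = array(1, geom$dim))
  expect_length(select_rois(big, grid, t_threshold = Inf), 0)
  expect_equal(select_rois(big, grid), grid$rois$roi_id)
  expect_error(select_rois(big, grid, t_threshold = 0), "positive")
  expect_error(select_rois(big, grid, t_threshold = -4), "positive")
})

test_that("the mirror rule adds the contralateral ROI and is idempotent", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  r <- grid$rois
  left <- r$roi_id[r$center_x < 0][1]
  mirrored <- apply_mirror_rule(left, grid)
  expect_length(mirrored, 2)
  i <- match(setdiff(mirrored, left), r$roi_id)
  expect_equal(r$center_x[i], -r$center_x[match(left, r$roi_id)])
  expect_equal(r$center_y[i], r$center_y[match(left, r$roi_id)])
  # idempotent on an already-bilateral selection
  expect_equal(apply_mirror_rule(mirrored, grid), mirrored)
  # closure: reflection-invariant wherever reflections exist
  aug <- apply_mirror_rule(sample(r$roi_id, 5), grid)
  expect_equal(apply_mirror_rule(aug, grid), aug)
  # asymmetric grid is rejected
  bad <- grid
  bad$origin_mm[1] <- bad$origin_mm[1] + 7
  expect_error(apply_mirror_rule(left, bad), "mirror-symmetric")
})

test_that("network allocation follows the sign of the ROI-mean group response", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  mp <- array(0, geom$dim)
  mp[grid$voxels[["1"]]] <- 0.09    # Table-2-scale activation
  mp[grid$voxels[["2"]]] <- -0.04   # deactivation
  group <- list(mean_psc = mp, t = mp)
  nw <- assign_networks(c(1, 2, 3), group, grid)
  expect_equal(unname(nw[c("1", "2", "3")]), c("CEN", "DMN", "none"))
  expect_error(assign_networks(integer(0), group, grid), "empty")
})

test_that("network means average member ROIs and flag empty networks", {
  nw <- c(`1` = "CEN", `2` = "CEN", `3` = "DMN")
  expect_equal(network_mean(c(`1` = 0.1, `2` = 0.2, `3` = -0.3), nw),
               list(cen_psc = 0.15, dmn_psc = -0.3))
  expect_warning(res <- network_mean(c(`1` = 0.1, `2` = 0.2),
                                     c(`1` = "CEN", `2` = "CEN")),
                 "DMN")
  expect_true(is.na(res$dmn_psc))
  # 18 CEN + 10 DMN values against a brute-force mean oracle
  set.seed(7)
  vals <- stats::setNames(stats::rnorm(28), as.character(1:28))
  nw28 <- stats::setNames(rep(c("CEN", "DMN"), c(18, 10)), as.character(1:28))
  res <- network_mean(vals, nw28)
  expect_equal(res$cen_psc, sum(vals[1:18]) / 18)
  expect_equal(res$dmn_psc, sum(vals[19:28]) / 10)
})

test_that("tumor-overlap statistics follow their definitions and bounds", {
  geom <- bold_geometry(c(10, 10, 10))
  grid <- build_roi_grid(geom)
  # hand-built mask covering 25 of ROI 1's 125 voxels
  m <- array(FALSE, geom$dim)
  m[grid$voxels[["1"]][1:25]] <- TRUE
  expect_equal(tumor_overlap_per_roi(list(m), grid, 1), 20)
  # second subject with no overlap halves the cohort average
  expect_equal(tumor_overlap_per_roi(list(m, array(FALSE, geom$dim)), grid, 1), 10)
  expect_equal(tumor_overlap_per_roi(list(array(FALSE, geom$dim)), grid, 2), 0)
  full <- array(TRUE, geom$dim)
  expect_equal(tumor_overlap_per_roi(list(full, full), grid, 3), 100)
  # per-subject: tumor covering half the voxels of one ROI among 8 ROIs
  sel <- grid$rois$roi_id
  m2 <- array(FALSE, geom$dim)
  m2[grid$voxels[["4"]][1:62]] <- TRUE
  expect_equal(tumor_overlap_per_subject(m2, grid, sel), 100 * 62 / 1000)
  expect_equal(tumor_overlap_per_subject(array(FALSE, geom$dim), grid, sel), 0)
  expect_equal(tumor_overlap_per_subject(full, grid, sel), 100)
  expect_error(tumor_overlap_per_subject(m2, grid, integer(0)), "empty")
  # monotone under mask growth
  grown <- m2
  grown[grid$voxels[["5"]][1:10]] <- TRUE
  expect_gte(tumor_overlap_per_subject(grown, grid, sel),
             tumor_overlap_per_subject(m2, grid, sel))
})

test_that("ellipsoidal tumor masks rasterize at the right volume", {
  geom <- bold_geometry(c(20, 20, 20))
  # tiny radii cover at most the single containing voxel
  tiny <- simulate_tumor_mask(c(1.5, 1.5, 1.5), rep(0.1, 3), geom)
  expect_lte(sum(tiny$mask), 1)
  # 22.5-mm sphere: volume within 15% of (4/3) pi r^3 ~ 47.7 cm^3
  sph <- simulate_tumor_mask(c(0, 0, 0), rep(22.5, 3), geom)
  analytic <- 4 / 3 * pi * 2.25^3
  expect_lt(abs(sph$volume_cm3 - analytic) / analytic, 0.15)
  expect_equal(sph$volume_cm3, sum(sph$mask) * 27 / 1000)
  expect_error(simulate_tumor_mask(c(0, 0, 0), c(-1, 1, 1), geom), "radii")
  expect_error(simulate_tumor_mask(c(500, 0, 0), rep(5, 3), geom), "outside")
  # mask outside all selected ROIs -> per-subject overlap 0
  grid <- build_roi_grid(geom)
  corner <- simulate_tumor_mask(c(-28, -28, -28), rep(4, 3), geom)
  far <- grid$rois$roi_id[grid$rois$center_x > 0]
  expect_equal(tumor_overlap_per_subject(corner, grid, far), 0)
})

test_that("grids export to a labeled atlas and ROI table", {
  geom <- bold_geometry(c(10, 10, 5))
  grid <- seeded_grid(geom)
  prefix <- file.path(withr::local_tempdir(), "grid")
  paths <- write_roi_grid(grid, prefix)
  lab <- read_nifti(paths[1])
  expect_equal(sort(unique(as.vector(lab$data))), grid$rois$roi_id)
  tab <- utils::read.csv(paths[2])
  expect_equal(tab$roi_id, grid$rois$roi_id)
  expect_true("network" %in% names(tab))
})
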