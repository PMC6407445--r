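# Synthetic anatomy: contour lofting and the parametric pelvis.

square_poly <- function(side = 10, x0 = 0, y0 = 0) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side), c(x0, y0))
}

circle_poly <- function(r = 5, n = 72, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

test_that("contour stacks validate their polygons", {
  expect_error(contour_stack(list(), 3.9), "zero slices")
  open_poly <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(contour_stack(list(list(open_poly)), 3.9), "not closed")
  expect_error(contour_stack(list(list(), list()), 3.9), "non-empty")
})

test_that("a stack of identical squares voxelises to the analytic prism", {
  stack <- contour_stack(rep(list(list(square_poly(10))), 7), 3.9)
  vol <- contours_to_volume(stack, voxel_mm = 0.5)
  v_num <- sum(vol$mask) * prod(vol$voxel_mm)
  v_ana <- 100 * 3.9 * 7  # 2730 mm^3
  expect_lt(abs(v_num - v_ana) / v_ana, 0.03)
})

test_that("a stack of circles voxelises to the analytic cylinder", {
  stack <- contour_stack(rep(list(list(circle_poly(5))), 6), 2.0)
  vol <- contours_to_volume(stack, voxel_mm = 0.5)
  v_num <- sum(vol$mask) * prod(vol$voxel_mm)
  v_ana <- pi * 25 * 12
  expect_lt(abs(v_num - v_ana) / v_ana, 0.05)
})

test_that("voxelised volumes converge to the analytic volume with grid refinement", {
  stack <- contour_stack(rep(list(list(circle_poly(5))), 6), 2.0)
  v_ana <- pi * 25 * 12
  err <- vapply(c(1.0, 0.5), function(h) {
    v <- contours_to_volume(stack, voxel_mm = h)
    abs(sum(v$mask) * prod(v$voxel_mm) - v_ana) / v_ana
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("enlarging every polygon produces a superset mask", {
  stack <- contour_stack(rep(list(list(circle_poly(4, cx = 1, cy = -1))), 5),
                         3.0)
  big <- contour_stack(rep(list(list(circle_poly(5.5, cx = 1, cy = -1))), 5),
                       3.0)
  grid <- list(voxel_mm = 0.5, extent_mm = c(16, 16, 19), origin_mm = c(-7, -9, -2))
  m1 <- contours_to_volume(stack, grid$voxel_mm, grid$extent_mm, grid$origin_mm)
  m2 <- contours_to_volume(big, grid$voxel_mm, grid$extent_mm, grid$origin_mm)
  expect_true(all(m2$mask[m1$mask]))
  expect_gt(sum(m2$mask), sum(m1$mask))
})

test_that("contour stacks round-trip through CSV", {
  stack <- contour_stack(list(list(square_poly(8)), list(circle_poly(3, 16))),
                         3.9)
  path <- tempfile(fileext = ".csv")
  write_contours_csv(stack, path)
  back <- read_contours_csv(path, 3.9)
  expect_equal(length(back$polygons), 2)
  expect_equal(back$polygons[[1]][[1]], unname(stack$polygons[[1]][[1]]))
})

test_that("the synthetic pelvis has the documented labels and conductivities", {
  tis <- make_synthetic_pelvis(seed = 7)
  codes <- tissue_labels()
  expect_setequal(unique(as.integer(tis$labels)),
                  unname(codes[c("fat", "bone", "colon")]))
  expect_equal(unname(tis$conductivity[c("fat", "bone", "colon")]),
               c(0.01, 0.02, 0.01))
  # same seed twice: bit-identical label grids
  tis2 <- make_synthetic_pelvis(seed = 7)
  expect_identical(tis$labels, tis2$labels)
  # different seed differs somewhere (jittered geometry)
  tis3 <- make_synthetic_pelvis(seed = 8)
  expect_false(identical(tis$labels, tis3$labels))
})

test_that("bone volume is near the analytic slab-minus-channels volume", {
  tis <- make_synthetic_pelvis(seed = 3)
  p <- tis$params
  v_bone_num <- sum(tis$labels == tissue_labels()[["bone"]]) *
    prod(tis$voxel_mm)
  slab <- diff(p$slab_x_mm) * diff(p$slab_y_mm) * diff(p$slab_z_mm)
  channels <- length(p$foramen_z_mm) * pi * (p$foramen_diameter_mm / 2)^2 *
    diff(p$slab_x_mm)
  v_bone_ana <- slab - channels
  # minus the part of the slab displaced by the colon tube (none by default:
  # the tube is anterior to the slab)
  expect_lt(abs(v_bone_num - v_bone_ana) / v_bone_ana, 0.2)
})

test_that("invalid pelvis parameters are rejected", {
  expect_error(make_synthetic_pelvis(foramen_diameter_mm = 70, seed = 1),
               "foramen")
})

test_that("the homogeneous model differs from the pelvis only in labels", {
  hom <- make_homogeneous()
  pel <- make_synthetic_pelvis(seed = 1)
  expect_equal(dim(hom$labels), dim(pel$labels))
  expect_equal(hom$voxel_mm, pel$voxel_mm)
  expect_equal(length(unique(as.integer(hom$labels))), 1L)
  expect_equal(unname(hom$conductivity[["fat"]]), 0.01)
})

test_that("tissue models round-trip through NIfTI + sidecar", {
  tis <- make_synthetic_pelvis(extent_mm = c(40, 40, 30), voxel_mm = 2,
                               slab_x_mm = c(10, 25), slab_y_mm = c(8, 32),
                               slab_z_mm = c(5, 25),
                               foramen_z_mm = 15, foramen_y_mm = 20,
                               rectum_centre_mm = c(32, 20),
                               rectum_radius_mm = 5, seed = 2)
  path <- tempfile(fileext = ".nii.gz")
  write_tissue_nifti(tis, path)
  back <- read_tissue_nifti(path)
  expect_equal(back$labels, tis$labels, ignore_attr = TRUE)
  expect_equal(back$voxel_mm, tis$voxel_mm, tolerance = 1e-6)
  expect_equal(back$conductivity[["bone"]], 0.02)
})

test_that("label grids demand complete conductivity tables", {
  lab <- array(c(1L, 2L, 3L, 99L), dim = c(4, 1, 1))
  expect_error(tissue_model(lab, 1), "99")
})
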