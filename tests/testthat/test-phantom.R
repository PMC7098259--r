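# Layered phantom geometry, conductivity assignment and NIfTI round trips.

test_that("nested shells label voxels by radial position", {
  ph <- make_layered_phantom(64, 1, c(20, 25, 28))
  d <- dim(ph$labels)
  ctr <- d / 2  # world mm
  r <- voxel_distance(d, 1, ctr)
  # center voxel: innermost compartment
  expect_equal(ph$labels[32, 32, 32], 1L)
  # a voxel between the GM and CSF radii is CSF
  expect_true(all(ph$labels[r > 25.6 & r < 27.4] == 3L))
  # inside WM radius all WM, outside CSF radius all background
  expect_true(all(ph$labels[r < 19.4] == 1L))
  expect_true(all(ph$labels[r > 28.6] == 0L))
  validate_phantom(ph)
})

test_that("phantom generation is deterministic and rejects bad geometry", {
  a <- make_layered_phantom(32, 1.5, c(10, 15, 20))
  b <- make_layered_phantom(32, 1.5, c(10, 15, 20))
  expect_identical(a$labels, b$labels)
  expect_error(make_layered_phantom(32, 1, c(10, 10, 12)), "strictly increasing")
  expect_error(make_layered_phantom(32, 1, c(25, 28, 30)), "out of bounds")
})

test_that("voxelized tissue volumes converge to the analytic shell volumes", {
  radii <- c(10, 12.5, 14)
  an <- analytic_shell_volumes(radii)
  frac_err <- function(voxel_mm) {
    ph <- make_layered_phantom(round(32 / voxel_mm), voxel_mm, radii)
    vox <- prod(ph$voxel_size_mm)
    got <- sapply(1:3, function(l) sum(ph$labels == l) * vox)
    abs(got - an) / an
  }
  e1 <- frac_err(1)
  expect_lt(max(e1), 0.05)          # within 5% at 1-mm voxels
  e05 <- frac_err(0.5)
  expect_lt(max(e05), max(e1))      # refinement improves the volumes
})

test_that("per-axis radii produce an asymmetric phantom that stays nested", {
  R <- rbind(c(8, 10, 9), c(11, 13, 12), c(13, 15, 14))
  ph <- make_layered_phantom(c(32, 36, 34), 1, R)
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  validate_phantom(ph)
})

test_that("conductivity assignment is a per-label lookup with zero background", {
  ph <- make_layered_phantom(32, 2, c(10, 12.5, 14))
  ph <- assign_conductivities(ph)
  expect_equal(unique(ph$conductivity_S_m[ph$labels == 1L]), 0.14)
  expect_equal(unique(ph$conductivity_S_m[ph$labels == 2L]), 0.33)
  expect_equal(unique(ph$conductivity_S_m[ph$labels == 3L]), 1.79)
  expect_true(all(ph$conductivity_S_m[ph$labels == 0L] == 0))
  # custom table, numeric label names
  ph2 <- assign_conductivities(ph, c(`1` = 0.2, `2` = 0.3, `3` = 1.5))
  expect_equal(unique(ph2$conductivity_S_m[ph2$labels == 1L]), 0.2)
  # a phantom with only one tissue present needs only that entry
  blk <- tissue_phantom(array(1L, dim = c(8, 8, 8)), 1)
  blk <- assign_conductivities(blk, c(WM = 0.2))
  expect_true(all(blk$conductivity_S_m == 0.2))
})

test_that("a missing conductivity entry names the offending label", {
  ph <- make_layered_phantom(32, 2, c(10, 12.5, 14))
  expect_error(assign_conductivities(ph, c(WM = 0.14, GM = 0.33)), "CSF")
})

test_that("NIfTI round trip preserves labels, maps and voxel size exactly", {
  ph <- make_layered_phantom(16, c(1, 1.5, 2), c(4, 5, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph, f)
  back <- read_labels_nifti(f)
  expect_identical(back$labels, ph$labels)
  expect_equal(back$voxel_size_mm, ph$voxel_size_mm)
  # float map round trip
  vol <- array(rnorm(16^3), dim = c(16, 16, 16))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, f2, c(1, 1.5, 2))
  back2 <- read_map_nifti(f2)
  expect_equal(back2$data, vol, ignore_attr = TRUE)
  expect_equal(back2$voxel_size_mm, c(1, 1.5, 2))
})

test_that("NIfTI label reader rejects unknown labels and non-3-D volumes", {
  lab <- array(0L, dim = c(8, 8, 8)); lab[4, 4, 4] <- 7L
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(lab, pixdim = c(1, 1, 1), datatype = "int16")
  RNifti::writeNifti(img, f, datatype = "int16")
  expect_error(read_labels_nifti(f), "7")
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), f4)
  expect_error(read_labels_nifti(f4), "3-D")
  expect_error(read_labels_nifti(tempfile()), "no such file")
})

test_that("constructor invariants catch malformed phantoms", {
  expect_error(tissue_phantom(array(5L, dim = c(8, 8, 8))), "unknown label")
  expect_error(tissue_phantom(array(1L, dim = c(4, 4, 4))), "8 voxels")
  expect_error(tissue_phantom(array(1L, dim = c(8, 8, 8)), voxel_size_mm = -1))
  lab <- array(1L, dim = c(8, 8, 8))
  sig <- array(0, dim = c(8, 8, 8))
  expect_error(tissue_phantom(lab, 1, conductivity_S_m = sig), "positive")
})
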