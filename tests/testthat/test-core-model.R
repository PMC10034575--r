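test_that("grid and mask constructors enforce their invariants", {
  expect_error(dose_grid(array(-1, c(2, 2, 2)), iso1), "non-negative")
  expect_error(dose_grid(array(NaN, c(2, 2, 2)), iso1), "finite")
  expect_error(dose_grid(array(1, c(2, 2)), iso1), "3D")
  expect_error(dose_grid(array(1, c(2, 2, 2)), c(1, 0, 1)), "spacing")
  expect_error(structure_mask(array(FALSE, c(2, 2, 2)), "CTV", iso1),
               "non-empty")
  # non-target structures may be empty
  expect_silent(structure_mask(array(FALSE, c(2, 2, 2)), "other", iso1))
  expect_error(displacement_field(array(Inf, c(2, 2, 2, 3)), iso1), "finite")
  expect_error(displacement_field(array(0, c(2, 2, 2, 2)), iso1),
               "nx, ny, nz, 3")
})

test_that("voxel centers map to physical coordinates as origin + index*spacing", {
  g <- dose_grid(array(0, c(4, 5, 6)), spacing = c(2, 1.5, 3),
                 origin = c(-10, 0, 5))
  # hand-computed corner cases
  expect_equal(drop(voxel_coords(g, cbind(1, 1, 1))), c(-10, 0, 5))
  expect_equal(drop(voxel_coords(g, cbind(4, 5, 6))),
               c(-10 + 3 * 2, 0 + 4 * 1.5, 5 + 5 * 3))
  expect_equal(voxel_volume(g), 2 * 1.5 * 3)
})

test_that("fraction and series records validate edit class, indices and prescription", {
  ser <- tiny_series(n_fractions = 2)
  f1 <- ser$fractions[[1]]
  expect_error(
    fraction_record(1, f1$ictv, f1$scheduled_dose, edit_class = 4),
    "edit_class")
  expect_error(fraction_record(0, f1$ictv, f1$scheduled_dose), ">= 1")
  expect_error(
    series_record(ser$reference_ctv, ser$reference_dose,
                  prescription_gy = 7, dose_per_fraction_gy = 2,
                  ptv_margin_mm = 5, fractions = ser$fractions),
    "prescription inconsistent")
  expect_error(
    series_record(ser$reference_ctv, ser$reference_dose,
                  prescription_gy = 4, dose_per_fraction_gy = 2,
                  ptv_margin_mm = 5,
                  fractions = list(f1, f1)),
    "unique")
  expect_error(
    series_record(ser$reference_ctv, ser$reference_dose,
                  prescription_gy = 0, dose_per_fraction_gy = 2,
                  ptv_margin_mm = 5, fractions = list()),
    "at least one fraction")
})

test_that("NRRD volumes round-trip in both encodings", {
  set.seed(5)
  vals <- array(runif(4 * 3 * 5, 0, 70), c(4, 3, 5))
  for (enc in c("raw", "gzip")) {
    p <- tempfile(fileext = ".nrrd")
    write_nrrd(vals, p, spacing = c(1, 2, 2.5), origin = c(-1, 0, 3),
               type = "double", encoding = enc)
    back <- read_nrrd(p)
    expect_identical(dim(back$values), dim(vals))
    expect_equal(back$values, vals, tolerance = 0)
    expect_equal(back$spacing, c(1, 2, 2.5))
    expect_equal(back$origin, c(-1, 0, 3))
  }
  m <- array(runif(60) < 0.4, c(4, 3, 5))
  p <- tempfile(fileext = ".nrrd")
  write_nrrd(m, p, spacing = iso1, type = "uint8")
  expect_identical(array(read_nrrd(p)$values, dim(m)), m)
  expect_error(read_nrrd(tempfile()), "not found")
})

test_that("a series round-trips through write_series/read_series", {
  ser <- tiny_series(n_fractions = 3, seed = 21)
  out <- tempfile()
  mp <- write_series(ser, out)
  back <- read_series(mp)
  expect_length(back$fractions, 3)
  # masks bit-exact
  expect_identical(back$reference_ctv$voxels, ser$reference_ctv$voxels)
  for (i in 1:3) {
    expect_identical(back$fractions[[i]]$ictv$voxels,
                     ser$fractions[[i]]$ictv$voxels)
    expect_identical(back$fractions[[i]]$edit_class,
                     ser$fractions[[i]]$edit_class)
    expect_identical(back$fractions[[i]]$delivered_plan,
                     ser$fractions[[i]]$delivered_plan)
    # doses within 1e-6 Gy per voxel
    expect_lt(max(abs(back$fractions[[i]]$adapted_dose$values -
                      ser$fractions[[i]]$adapted_dose$values)), 1e-6)
    expect_lt(max(abs(back$fractions[[i]]$dvf$vectors -
                      ser$fractions[[i]]$dvf$vectors)), 1e-6)
  }
  expect_equal(back$prescription_gy, ser$prescription_gy)
  unlink(out, recursive = TRUE)
})

test_that("read_series reports broken manifests precisely", {
  ser <- tiny_series(n_fractions = 3, seed = 31)
  out <- tempfile()
  mp <- write_series(ser, out)

  # missing volume file is named
  file.remove(file.path(out, "fx02_ictv.nrrd"))
  expect_error(read_series(mp), "fx02_ictv")

  # fraction 3 mask with a mismatched shape is attributed to fraction 3
  write_nrrd(array(TRUE, c(4, 4, 4)), file.path(out, "fx02_ictv.nrrd"),
             spacing = ser$reference_dose$spacing, type = "uint8")
  write_nrrd(array(TRUE, c(4, 4, 4)), file.path(out, "fx03_ictv.nrrd"),
             spacing = ser$reference_dose$spacing, type = "uint8")
  write_nrrd(ser$fractions[[2]]$ictv$voxels, file.path(out, "fx02_ictv.nrrd"),
             spacing = ser$reference_dose$spacing, type = "uint8")
  expect_error(read_series(mp), "fraction 3")

  # out-of-range edit class is rejected
  write_nrrd(ser$fractions[[3]]$ictv$voxels, file.path(out, "fx03_ictv.nrrd"),
             spacing = ser$reference_dose$spacing, type = "uint8")
  m <- jsonlite::read_json(mp)
  m$fractions[[1]]$edit_class <- 4
  jsonlite::write_json(m, mp, auto_unbox = TRUE, digits = NA)
  expect_error(read_series(mp), "edit_class")
  unlink(out, recursive = TRUE)
})
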