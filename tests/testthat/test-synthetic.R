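test_that("the reference plan covers the CTV and is bounded by the prescription", {
  cfg <- sim_config(grid_shape = c(32, 32, 32), spacing_mm = c(3, 3, 3),
                    ctv_semiaxes_mm = c(18, 15, 15), seed = 1)
  ref <- make_reference(cfg)
  rx <- cfg$dose_per_fraction_gy
  ep <- endpoints(ref$dose, ref$ctv, rx)
  chk <- coverage_check(ep, rx)
  expect_true(chk$all_pass)
  expect_gt(ep$v100, 95)
  expect_gt(ep$d98, 0.98 * rx)
  expect_lte(max(ref$dose$values), 1.02 * rx)
  # near-binary falloff as the penumbra vanishes
  cfg_sharp <- sim_config(grid_shape = c(32, 32, 32), spacing_mm = c(3, 3, 3),
                          ctv_semiaxes_mm = c(18, 15, 15),
                          penumbra_mm = 0.01, seed = 1)
  ref_sharp <- make_reference(cfg_sharp)
  outside <- ref_sharp$dose$values[!ref_sharp$ptv$voxels]
  expect_lt(max(outside), 1e-6 * rx)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- tiny_series(n_fractions = 2, seed = 99)
  s2 <- tiny_series(n_fractions = 2, seed = 99)
  expect_identical(s1$fractions[[1]]$ictv$voxels, s2$fractions[[1]]$ictv$voxels)
  expect_identical(s1$fractions[[2]]$dvf$vectors, s2$fractions[[2]]$dvf$vectors)
  expect_identical(s1$fractions[[1]]$edit_class, s2$fractions[[1]]$edit_class)
  s3 <- tiny_series(n_fractions = 2, seed = 100)
  expect_false(identical(s3$fractions[[1]]$dvf$vectors,
                         s1$fractions[[1]]$dvf$vectors))
  c1 <- generate_cohort(3, sim_config(grid_shape = c(16, 16, 16),
                                      spacing_mm = c(6, 6, 6),
                                      ctv_semiaxes_mm = c(20, 16, 16),
                                      n_fractions = 2), seed = 5)
  c2 <- generate_cohort(3, sim_config(grid_shape = c(16, 16, 16),
                                      spacing_mm = c(6, 6, 6),
                                      ctv_semiaxes_mm = c(20, 16, 16),
                                      n_fractions = 2), seed = 5)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$series[[3]]$fractions[[2]]$ictv$voxels,
                   c2$series[[3]]$fractions[[2]]$ictv$voxels)
})

test_that("zero drift reproduces the reference plan exactly", {
  ser <- tiny_series(n_fractions = 2, drift = 0, amp = 0, seed = 77)
  f <- ser$fractions[[1]]
  expect_identical(f$ictv$voxels, ser$reference_ctv$voxels)
  expect_equal(f$adapted_dose$values, f$scheduled_dose$values,
               tolerance = 1e-12)
  expect_true(all(f$dvf$vectors == 0))
})

test_that("a translation far beyond margin+penumbra wrecks only the scheduled plan", {
  cfg <- sim_config(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3),
                    ctv_semiaxes_mm = c(18, 15, 15), n_fractions = 1,
                    margin_mm = 5, seed = 2)
  ref <- make_reference(cfg)
  zero_elastic <- replicate(3, array(0, dim = cfg$grid_shape),
                            simplify = FALSE)
  fr <- sample_fraction(ref, 1, translation = c(30, 0, 0),
                        elastic = zero_elastic)
  ser <- series_record(ref$ctv, ref$dose, cfg$dose_per_fraction_gy,
                       cfg$dose_per_fraction_gy, cfg$margin_mm, list(fr))
  dev <- series_deviations(ser, characteristics = "min_dose")
  expect_lt(dev$pct_dev_scheduled, -50)
  expect_lt(abs(dev$pct_dev_adapted), 1)
})

test_that("centroid drift of the simulated target recovers the configured SD", {
  cfg <- sim_config(grid_shape = c(32, 32, 32), spacing_mm = c(3, 3, 3),
                    ctv_semiaxes_mm = c(18, 15, 15), n_fractions = 1,
                    drift_sd_mm = 4, deform_amp_mm = 0, seed = 123)
  ref <- make_reference(cfg)
  ref_centroid <- colMeans(voxel_coords(ref$ctv,
                                        which(ref$ctv$voxels, arr.ind = TRUE)))
  set.seed(2024)
  disp <- t(vapply(1:200, function(i) {
    fr <- sample_fraction(ref, 1)
    colMeans(voxel_coords(fr$ictv, which(fr$ictv$voxels, arr.ind = TRUE))) -
      ref_centroid
  }, numeric(3)))
  pooled_sd <- sqrt(mean(apply(disp, 2, stats::var)))
  expect_lt(abs(pooled_sd - 4) / 4, 0.15)
})

test_that("adapted deviations stay near zero while scheduled deviations widen with drift", {
  cfg <- sim_config(grid_shape = c(32, 32, 32), spacing_mm = c(3, 3, 3),
                    ctv_semiaxes_mm = c(18, 15, 15), n_fractions = 4,
                    drift_sd_mm = 6, deform_amp_mm = 2, seed = 7)
  ser <- simulate_series(cfg)
  dev <- series_deviations(ser, characteristics = "geud")
  expect_lt(max(abs(dev$pct_dev_adapted)), 5)
  expect_lt(min(dev$pct_dev_scheduled), min(dev$pct_dev_adapted))
})
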