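test_that("DVH of uniform and two-level fields matches construction", {
  msk <- full_mask()
  dvh <- compute_dvh(uniform_grid(60), msk, 0.1)
  expect_equal(sum(dvh$differential), 1, tolerance = 1e-9)
  expect_equal(sum(dvh$differential > 0), 1)   # single occupied bin
  expect_equal(dvh$cumulative[1], 1)
  expect_equal(dvh$structure_volume_ml, 1.0)   # 1000 voxels of 1 mm^3
  expect_true(all(diff(c(dvh$cumulative, dvh$cum_top)) <= 1e-12))

  d2 <- compute_dvh(two_level_grid(60, 40), msk, 0.1)
  occupied <- which(d2$differential > 0)
  expect_length(occupied, 2)
  expect_equal(unname(d2$differential[occupied]), c(0.5, 0.5))

  expect_error(compute_dvh(uniform_grid(),
                           structure_mask(array(FALSE, c(10, 10, 10)),
                                          "other", iso1), 0.1),
               "empty structure")
})

test_that("differential DVH equals a direct histogram for random fields", {
  set.seed(101)
  msk <- full_mask(c(8, 8, 8))
  for (rep in 1:5) {
    g <- random_dose_grid()
    dvh <- compute_dvh(g, msk, 0.5)
    expect_equal(sum(dvh$differential), 1, tolerance = 1e-9)
    direct <- hist(as.numeric(g$values),
                   breaks = dvh$bin_edges, plot = FALSE)$counts / 512
    expect_equal(dvh$differential, direct, tolerance = 1e-12)
  }
})

test_that("Dx% interpolates the cumulative curve and tracks the voxel-sort answer", {
  msk <- full_mask()
  dvh_u <- compute_dvh(uniform_grid(60), msk, 0.1)
  expect_equal(dose_at_volume(dvh_u, 95), 60)

  d2 <- compute_dvh(two_level_grid(60, 40), msk, 0.1)
  # 95% coverage is governed by the cold half: interpolation inside the
  # bin just above 40 Gy
  expect_gte(dose_at_volume(d2, 95), 40)
  expect_lte(dose_at_volume(d2, 95), 40 + 0.1)
  expect_equal(oracle_dx(as.numeric(two_level_grid()$values), 95), 40)
  expect_equal(dose_at_volume(d2, 100), 40)  # min in-structure bin edge

  expect_error(dose_at_volume(d2, 0), "in \\(0, 100")

  # random fields: DVH answer within one bin width of exact order statistic
  set.seed(77)
  msk8 <- full_mask(c(8, 8, 8))
  bw <- 0.25
  for (rep in 1:100) {
    g <- random_dose_grid()
    dvh <- compute_dvh(g, msk8, bw)
    for (x in c(50, 95, 98)) {
      exact <- oracle_dx(as.numeric(g$values), x)
      expect_lt(abs(dose_at_volume(dvh, x) - exact), bw + 1e-9)
    }
  }
})

test_that("Vx interpolates volume at dose and matches voxel counts", {
  msk <- full_mask()
  dvh_u <- compute_dvh(uniform_grid(60), msk, 0.1)
  expect_equal(volume_at_dose(dvh_u, 57), 100)
  expect_equal(volume_at_dose(dvh_u, 61), 0)
  d2 <- compute_dvh(two_level_grid(60, 40), msk, 0.1)
  expect_equal(volume_at_dose(d2, 57), 50)  # direct voxel count
  expect_error(volume_at_dose(d2, -1), ">= 0")
})

test_that("gEUD reproduces closed forms and limits", {
  msk <- full_mask()
  dvh_u <- compute_dvh(uniform_grid(60), msk, 0.05)
  for (a in c(-200, -20, -1, 1, 8)) expect_equal(geud(dvh_u, a), 60)

  # voxel-exact two-level case against direct high-precision summation
  direct <- (0.5 * 60^-20 + 0.5 * 40^-20)^(-1 / 20)
  expect_equal(geud(list(d = c(60, 40), v = c(0.5, 0.5)), -20), direct,
               tolerance = 1e-9)
  # a = 1 is the mean dose
  expect_equal(geud(list(d = c(60, 40), v = c(0.5, 0.5)), 1), 50,
               tolerance = 1e-12)
  # a -> -Inf converges to the minimum dose
  expect_lt(abs(geud(list(d = c(60, 40), v = c(0.5, 0.5)), -200) - 40) / 40,
            0.005)
  expect_error(geud(dvh_u, 0), "a = 0")
  expect_warning(g0 <- geud(list(d = c(0, 60), v = c(0.5, 0.5)), -20),
                 "zero dose")
  expect_equal(g0, 0)
})

test_that("gEUD is monotone in a and bounded by min/mean/max", {
  set.seed(55)
  msk <- full_mask(c(8, 8, 8))
  for (rep in 1:5) {
    g <- random_dose_grid()
    dvh <- compute_dvh(g, msk, 0.2)
    vals <- vapply(c(-200, -20, -5, 1, 5, 20), function(a) geud(dvh, a),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
    expect_gte(geud(dvh, -20), dvh$min_dose)
    expect_lte(geud(dvh, -20), dvh$mean_dose + 0.2)
    expect_lte(geud(dvh, 20), dvh$max_dose)
  }
})

test_that("gEUD converges under bin refinement on a smooth field", {
  # smooth radial falloff field
  sh <- c(16, 16, 16)
  ax <- (0:15) - 7.5
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  g <- dose_grid(array(60 / (1 + exp(r / 6 - 2)), dim = sh), iso1)
  msk <- full_mask(sh)
  g1 <- geud(compute_dvh(g, msk, 0.02), -20)
  g2 <- geud(compute_dvh(g, msk, 0.01), -20)
  expect_lt(abs(g1 - g2) / g2, 0.001)
})

test_that("endpoint sets satisfy the coverage ordering invariants", {
  set.seed(9)
  msk <- full_mask(c(8, 8, 8))
  for (rep in 1:10) {
    g <- random_dose_grid()
    ep <- endpoints(g, msk, prescription_gy = 55, a = -20)
    expect_lte(ep$min_dose, ep$d99 + 1e-9)
    expect_lte(ep$d99, ep$d98 + 1e-9)
    expect_lte(ep$d98, ep$d95 + 1e-9)
    expect_true(ep$v95 >= 0 && ep$v95 <= 100)
    expect_lte(ep$v100, ep$v95 + 1e-9)
    expect_equal(ep$min_dose, min_dose(g, msk))
  }
  one_cold <- array(60, c(10, 10, 10)); one_cold[3, 4, 5] <- 12
  expect_equal(min_dose(dose_grid(one_cold, iso1), full_mask()), 12)
})
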