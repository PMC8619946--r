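test_that("EF and FPF are guarded ratio computations", {
  expect_equal(compute_ef(15, 15), 100)
  expect_equal(compute_ef(13.5, 15), 90)
  expect_error(compute_ef(1, 0), "'MD' must be > 0")
  expect_error(compute_ef(16, 15), "ED")
  expect_equal(compute_fpf(12, 12), 100)
  expect_equal(compute_fpf(0, 12), 0)
  expect_equal(compute_fpf(3, 12), 25)
  expect_error(compute_fpf(3, 0), "'ED' must be > 0")
})

test_that("stage binning conserves mass with half-open bin edges", {
  cuts <- ngi_cutoffs_60lpm()
  set.seed(9)
  d <- runif(500, 0.1, 15)
  mass <- runif(500)
  st <- bin_to_stages(d, mass)
  expect_equal(sum(st$mass), sum(mass), tolerance = 1e-12)
  # above the top cut-off lands in the induction-port bin
  st1 <- bin_to_stages(10, 1)
  expect_equal(st1$mass[st1$label == "IP"], 1)
  # particles straddling one cut-off land on different stages
  st2 <- bin_to_stages(c(4.47, 4.45), c(1, 1))
  expect_equal(st2$mass[st2$label == "S2"], 1)
  expect_equal(st2$mass[st2$label == "S3"], 1)
  # a diameter exactly at a cut-off belongs to that stage (lower edge closed)
  st3 <- bin_to_stages(2.82, 1)
  expect_equal(st3$mass[st3$label == "S3"], 1)
  expect_error(bin_to_stages(1, 1, cutoffs = c(2, 3)), "decreasing")
})

test_that("two symmetric stages put the MMAD at the log midpoint exactly", {
  st <- stage_table(c("S2", "S3", "MOC"), c(4.46, 2.82, NA), c(30, 40, 30))
  res <- suppressWarnings(mmad_gsd(st))
  expect_equal(res$mmad_um, sqrt(4.46 * 2.82), tolerance = 1e-12)
  # the +-1 probit points are not bracketed by a 70/30 curve: GSD is NA
  expect_true(is.na(res$gsd))
  expect_warning(mmad_gsd(st), "GSD")
})

test_that("an exact lognormal stage table returns its own median and spread", {
  st <- lognormal_stage_table(4, 2)
  res <- mmad_gsd(st)
  # a lognormal is a straight line in probit-log space: recovery is exact
  expect_equal(res$mmad_um, 4, tolerance = 1e-6)
  expect_equal(res$gsd, 2, tolerance = 1e-6)
  # a second parameterization, against the closed-form CDF oracle
  st2 <- lognormal_stage_table(3, 1.8)
  res2 <- mmad_gsd(st2)
  expect_equal(res2$mmad_um, 3, tolerance = 0.02)
  expect_equal(res2$gsd, 1.8, tolerance = 0.02)
})

test_that("sampled lognormal aerosols recover MMAD within 3% and GSD within 5%", {
  # cases chosen inside the impactor's bracketing range: the +-1 probit
  # diameters must fall between the top (8.06 um) and bottom (0.34 um)
  # cut-offs, i.e. median * gsd < 8.06, or the no-extrapolation rule
  # (rightly) refuses a GSD
  for (case in list(c(2, 1.5, 101), c(4, 2, 202), c(3, 2.5, 303))) {
    set.seed(case[3])
    d <- rlnorm(1e5, log(case[1]), log(case[2]))
    st <- bin_to_stages(d, rep(1, 1e5))
    res <- mmad_gsd(st)
    expect_equal(res$mmad_um, case[1], tolerance = 0.03)
    expect_equal(res$gsd, case[2], tolerance = 0.05)
  }
})

test_that("MMAD refuses to extrapolate outside the measured curve", {
  # all mass below the lowest cut-off
  st <- bin_to_stages(rep(0.2, 10), rep(1, 10))
  expect_error(mmad_gsd(st), "refusing to extrapolate|fewer than two")
  # all mass above the top cut-off
  st2 <- bin_to_stages(rep(12, 10), rep(1, 10))
  expect_error(mmad_gsd(st2), "refusing to extrapolate|fewer than two")
})

test_that("MMAD scales with the diameters; GSD is scale-free", {
  set.seed(4)
  d <- rlnorm(2e4, log(4), log(2))
  st <- bin_to_stages(d, rep(1, 2e4))
  res <- mmad_gsd(st)
  c_scale <- 1.7
  st_scaled <- bin_to_stages(c_scale * d, rep(1, 2e4),
                             cutoffs = c_scale * ngi_cutoffs_60lpm())
  res_scaled <- mmad_gsd(st_scaled)
  expect_equal(res_scaled$mmad_um, c_scale * res$mmad_um, tolerance = 1e-9)
  expect_equal(res_scaled$gsd, res$gsd, tolerance = 1e-9)
})

test_that("FPD reads the log-probability curve at the respirable cut-off", {
  st <- lognormal_stage_table(4, 2)
  # cut-off at a stage boundary reproduces that stage's cumulative undersize
  fp <- fpd_from_curve(st, ED = 1, cutoff_um = 2.82)
  expect_equal(fp$fpd, plnorm(2.82, log(4), log(2)), tolerance = 1e-6)
  # median-diameter aerosol: FPF at the median is 50%
  st5 <- lognormal_stage_table(5, 2)
  fp5 <- fpd_from_curve(st5, ED = 1, cutoff_um = 5)
  expect_equal(fp5$fpf_pct, 50, tolerance = 2)
  # widening the cut-off can only increase the fine dose
  fp_tsi <- fpd_from_curve(st, ED = 1, cutoff_um = 6.4)
  fp_ngi <- fpd_from_curve(st, ED = 1, cutoff_um = 5)
  expect_gte(fp_tsi$fpd, fp_ngi$fpd)
  expect_error(fpd_from_curve(st, ED = 1, cutoff_um = 50),
               "outside the interpolable")
})

test_that("aero_summary ties the dose metrics together from one table", {
  st <- synthetic_stage_table(mmad_um = 4, gsd = 2, seed = 77,
                              device_fraction = 0.1)
  a <- aero_summary(st)
  expect_equal(a$MD, 1, tolerance = 1e-9)
  expect_equal(a$ED, 0.9, tolerance = 1e-9)
  expect_equal(a$EF_pct, 90, tolerance = 1e-9)
  expect_equal(a$MMAD_um, 4, tolerance = 0.05)
  expect_equal(a$GSD, 2, tolerance = 0.05)
  expect_true(a$FPD <= a$ED)
  expect_equal(a$FPF_pct, 100 * a$FPD / a$ED, tolerance = 1e-9)
  # regenerating with the same seed is bit-identical
  st_again <- synthetic_stage_table(mmad_um = 4, gsd = 2, seed = 77,
                                    device_fraction = 0.1)
  expect_identical(st$mass, st_again$mass)
})
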