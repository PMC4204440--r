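test_that("Hill activation matches closed-form values and limits", {
  # half-activation at EC50 holds exactly for arbitrary parameters
  for (p in list(hill_params(0.25, 1.1), hill_params(1.78, 1.43),
                 hill_params(40, 1))) {
    expect_identical(hill_activation(p$ec50, p), 0.5)
    expect_identical(hill_activation(0, p), 0)
  }
  # longhand evaluation of the Hill ratio
  expect_equal(hill_activation(1.1, hill_params(0.25, 1.1)),
               1.1^1.1 / (1.1^1.1 + 0.25^1.1))
  expect_equal(hill_activation(1.1, hill_params(0.25, 1.1)), 0.836,
               tolerance = 1e-3)
})

test_that("Hill activation is strictly increasing and bounded in [0, 1)", {
  set.seed(11)
  for (k in 1:20) {
    p <- hill_params(exp(runif(1, -3, 2)), runif(1, 0.5, 3))
    g <- sort(exp(runif(50, -6, 8)))
    a <- hill_activation(g, p)
    expect_true(all(diff(a) > 0))
    expect_true(all(a >= 0 & a < 1))
  }
  expect_error(hill_activation(-1, hill_params(1, 1)), "gly")
  expect_error(hill_params(0, 1), "ec50")
  expect_error(hill_params(1, -2), "slope")
})

test_that("effective conductance combines potentiation and internalization", {
  pd <- synapse_class_pd(ee = hill_params(2, 1.5), ei = hill_params(1, 1))
  expect_equal(effective_conductance(2, "ee", pd), 0.5)
  # internalization EC50 at the evaluated glycine halves the response
  pd_int <- synapse_class_pd(ee = hill_params(2, 1.5),
                             ei = hill_params(1, 1),
                             internalization_ee = hill_params(2, 1))
  expect_equal(effective_conductance(2, "ee", pd_int),
               0.5 * effective_conductance(2, "ee", pd))
  # independent two-factor hand computation
  pd2 <- synapse_class_pd(ee = hill_params(0.35, 1.84),
                          ei = hill_params(0.25, 1.1),
                          internalization_ee = 40)
  pot <- 10^1.84 / (10^1.84 + 0.35^1.84)
  surv <- 1 - 10 / (10 + 40)
  expect_equal(effective_conductance(10, "ee", pd2), pot * surv)
  # a bare EC50 for internalization implies slope 1
  expect_equal(pd2$internalization_ee$slope, 1)
})

test_that("per-subunit averages reproduce the published table", {
  avg <- subunit_averages(nr2_hill_studies())
  avg <- avg[match(c("NR2A", "NR2B", "NR2C", "NR2D"), avg$subunit), ]
  expect_equal(round(avg$ec50_uM, 2), c(1.78, 0.83, 0.36, 0.77))
  expect_equal(round(avg$hill_slope, 2), c(1.43, 1.77, 1.66, 1.21))
  # single-record table returns that record
  one <- as_subunit_study_table(
    data.frame(study = "s", subunit = "NR2A", ec50_uM = 2.2,
               hill_slope = 1.4))
  expect_equal(subunit_averages(one)$ec50_uM, 2.2)
  # all-missing subunit is an explicit error, never a zero
  bad <- as_subunit_study_table(
    data.frame(study = "s", subunit = "NR2D", ec50_uM = NA,
               hill_slope = 1))
  expect_error(subunit_averages(bad), "no EC50 data")
})

test_that("subunit tables round-trip through delimited text", {
  t1 <- nr2_hill_studies()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subunit_table(t1, path)
  t2 <- read_subunit_table(path)
  expect_equal(t2$ec50_uM, t1$ec50_uM)
  expect_equal(sum(is.na(t2$ec50_uM)), 1)  # the blank NR2D cell survives
})

test_that("e-i over e-e ratio has the expected values and limits", {
  expect_equal(ei_over_ee_ratio(c(0.1, 1, 50), pd_flat()), rep(1, 3))
  expect_equal(ei_over_ee_ratio(1e6, pd_reference()), 1, tolerance = 1e-4)
  # reported figure: ~0.93-0.94 near 1.1 uM for these parameters
  expect_equal(ei_over_ee_ratio(1.1, pd_reference()), 0.94, tolerance = 5e-3)
  # with the shallower e-i slope the small-glycine limit diverges
  expect_gt(ei_over_ee_ratio(1e-4, pd_reference()), 100)
  expect_error(ei_over_ee_ratio(0, pd_reference()), "gly")
})

test_that("ratio extremum search agrees with a brute-force grid oracle", {
  cases <- list(c(0.35, 1.84, 0.25, 1.1), c(0.35, 2, 0.2, 1),
                c(0.1, 2, 0.05, 1), c(0.25, 2, 0.21, 1))
  for (cs in cases) {
    pd <- synapse_class_pd(ee = hill_params(cs[1], cs[2]),
                           ei = hill_params(cs[3], cs[4]))
    got <- find_ratio_extremum(pd)
    want <- oracle_ratio_min(cs[1], cs[2], cs[3], cs[4])
    expect_true(got$is_interior_minimum)
    expect_equal(got$ratio_star, want$ratio, tolerance = 1e-6)
    expect_lt(abs(log(got$gly_star / want$gly)), log(want$step) * 2)
  }
})

test_that("flat and monotone ratios are not flagged as interior minima", {
  expect_false(find_ratio_extremum(pd_flat())$is_interior_minimum)
  # e-i slope above e-e slope with larger e-i EC50: monotone ratio
  pd_mono <- synapse_class_pd(ee = hill_params(0.2, 1),
                              ei = hill_params(0.4, 1.5))
  got <- find_ratio_extremum(pd_mono)
  expect_false(got$is_interior_minimum)
  want <- oracle_ratio_min(0.2, 1, 0.4, 1.5)
  expect_false(want$interior)
})

test_that("dose-response classification separates the three regimes", {
  expect_identical(classify_dose_response(pd_beneficial()),
                   "beneficial_U")
  expect_identical(classify_dose_response(pd_flat()), "monotonic")
  # scaled-down EC50s push the minimum below the physiological band
  pd_sub <- synapse_class_pd(ee = hill_params(0.1, 2),
                             ei = hill_params(0.05, 1))
  want <- oracle_ratio_min(0.1, 2, 0.05, 1)
  expect_lt(want$gly, 0.5)
  expect_identical(classify_dose_response(pd_sub),
                   "subphysiological_minimum")
})

test_that("the beneficial region grows with the e-e/e-i slope ratio", {
  ec50s <- exp(seq(log(0.05), log(2), length.out = 8))
  counts <- classification_map(ec50s, ec50s,
                               slope_ratios = c(1, 1.5, 2),
                               n_grid = 400)
  expect_true(all(diff(counts$beneficial_U) >= 0))
  expect_equal(counts$beneficial_U[1], 0)  # equal slopes: never beneficial
  expect_gt(counts$beneficial_U[3], 0)
})

test_that("dose-response curves round-trip with their metadata sidecar", {
  cur <- dose_response_curve(c(0.1, 1, 10), c(1, 1.4, 1.2),
                             what = "ratio")
  expect_error(dose_response_curve(c(1, 1), c(0, 0)), "increasing")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dose_response(cur, path)
  back <- read_dose_response(path)
  expect_equal(back$response, cur$response)
  expect_identical(attr(back, "what"), "ratio")
})
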