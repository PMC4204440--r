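test_that("competitive occupancy matches closed forms", {
  ctx <- synapse_context(nt_conc = 10, nt_ki = 10)
  # neurotransmitter alone at its Ki occupies (and activates) half
  expect_equal(steady_state_activation(ctx)$activation, 0.5)
  # neutral antagonist at 10x its Ki with NT at its Ki
  res <- steady_state_activation(
    ctx, data.frame(concentration = 100, ki = 10,
                    intrinsic_activity = 0))
  expect_equal(res$activation, 1 / 12)
  expect_equal(res$occupancy[["drug1"]], 10 / 12)
  # an infinitely weak drug changes nothing
  res2 <- steady_state_activation(
    ctx, data.frame(concentration = 100, ki = 1e12,
                    intrinsic_activity = 0))
  expect_equal(res2$activation, 0.5, tolerance = 1e-9)
  expect_error(
    steady_state_activation(ctx, data.frame(concentration = rep(1, 5),
                                            ki = 1,
                                            intrinsic_activity = 0)),
    "at most 4")
})

test_that("occupancies and the free fraction conserve the receptor pool", {
  set.seed(31)
  for (k in 1:20) {
    ctx <- synapse_context(nt_conc = exp(runif(1, 0, 6)),
                           nt_ki = exp(runif(1, 0, 6)))
    nd <- sample(0:4, 1)
    drugs <- if (nd > 0) {
      data.frame(concentration = exp(runif(nd, 0, 6)),
                 ki = exp(runif(nd, 0, 6)),
                 intrinsic_activity = runif(nd))
    } else {
      NULL
    }
    occ <- steady_state_activation(ctx, drugs)$occupancy
    expect_equal(sum(occ), 1)
  }
})

test_that("activation is monotone in antagonist and agonist levels", {
  ctx <- synapse_context(nt_conc = 20, nt_ki = 10)
  concs <- c(1, 10, 100, 1000)
  antag <- vapply(concs, function(cc) {
    steady_state_activation(ctx, data.frame(
      concentration = cc, ki = 15, intrinsic_activity = 0))$activation
  }, numeric(1))
  expect_true(all(diff(antag) < 0))
  agon <- vapply(concs, function(cc) {
    steady_state_activation(ctx, data.frame(
      concentration = cc, ki = 15, intrinsic_activity = 1))$activation
  }, numeric(1))
  expect_true(all(diff(agon) > 0))
})

test_that("relative activation is a scale-free normalised change", {
  expect_equal(relative_effect(0.4, 0.4), 0)
  expect_equal(relative_effect(0.6, 0.4), 0.5)
  expect_equal(relative_effect(0.3 * 7, 0.2 * 7),
               relative_effect(0.3, 0.2))
  expect_error(relative_effect(0.5, 0), "control")
})

test_that("occupancy inversion round-trips through the forward model", {
  ctx <- synapse_context(nt_conc = 10, nt_ki = 10)
  # with NT at its Ki, half occupancy needs twice the Ki
  expect_equal(occupancy_to_concentration(0.5, ki = 7, ctx), 14)
  # effectively no NT competition: concentration equals Ki
  ctx0 <- synapse_context(nt_conc = 1e-9, nt_ki = 10)
  expect_equal(occupancy_to_concentration(0.5, ki = 7, ctx0), 7,
               tolerance = 1e-6)
  # round trip, including under autoreceptor feedback
  for (ctx_k in list(ctx, synapse_context(10, 10, feedback_gain = 0.6))) {
    for (occ in c(0.1, 0.45, 0.9)) {
      conc <- occupancy_to_concentration(occ, ki = 12, ctx_k)
      fwd <- steady_state_activation(
        ctx_k, data.frame(concentration = conc, ki = 12,
                          intrinsic_activity = 0))
      expect_equal(fwd$occupancy[["drug1"]], occ, tolerance = 1e-6)
    }
  }
  # monotone in the target occupancy
  cs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), occupancy_to_concentration,
               numeric(1), ki = 12, ctx = ctx)
  expect_true(all(diff(cs) > 0))
  expect_error(occupancy_to_concentration(1, 10, ctx), "occupancy")
})

test_that("autoreceptor feedback raises release under antagonist block", {
  ctx <- synapse_context(nt_conc = 50, nt_ki = 20, feedback_gain = 0.8)
  res <- steady_state_activation(
    ctx, data.frame(concentration = 200, ki = 20,
                    intrinsic_activity = 0))
  # blocking the autoreceptor lowers its activation below baseline,
  # which disinhibits release
  expect_gt(res$release_scale, 1)
  # without drugs the fixed point is the drug-free baseline
  expect_equal(steady_state_activation(ctx)$release_scale, 1,
               tolerance = 1e-7)
})

test_that("affinity tables round-trip and default intrinsic activity", {
  x <- data.frame(drug = c("a", "b"), receptor = c("D2", "D2"),
                  ki_nM = c(5, 50))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  back <- read_affinity_table(path)
  expect_equal(back$intrinsic_activity, c(0, 0))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_affinity_table(back, path2)
  expect_equal(read_affinity_table(path2)$ki_nM, c(5, 50))
})
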