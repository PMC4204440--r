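test_that("Kir2 current matches the closed form over random states", {
  set.seed(41)
  p <- kir_params()
  for (k in 1:100) {
    v <- runif(1, -130, 0)
    u <- runif(1, 0, 2)
    want <- u * (1.2 / (1 + exp(-(v + 111) / -11))) * (v + 90)
    expect_equal(kir2_current(v, u, p), want)
  }
  expect_equal(kir2_current(-90, 1, p), 0)   # at the K+ reversal
  expect_equal(kir2_current(-120, 0, p), 0)  # no D1 scale, no current
})

test_that("the printed Kir2 sign convention gives inward rectification", {
  p <- kir_params()
  g <- function(v) 1.2 / (1 + exp(-(v - p$v_h) / p$v_c))
  # half-activation exactly at v_h: g = 0.6 mS/cm2, I = -12.6 uA/cm2
  expect_equal(g(p$v_h), p$g_bar / 2)
  expect_equal(kir2_current(p$v_h, 1, p), 0.6 * (-111 + 90))
  expect_equal(kir2_current(p$v_h, 1, p), -12.6)
  # conductance shuts with depolarisation and saturates when
  # hyperpolarised (v_c = -11 mV)
  vs <- seq(-150, 0, by = 10)
  expect_true(all(diff(g(vs)) < 0))
  expect_equal(g(-1000), p$g_bar, tolerance = 1e-9)
  expect_lt(g(100), 1e-6)
  # D1 up-modulation deepens the stabilising current below E_K
  expect_lt(kir2_current(-120, 1.2, p), kir2_current(-120, 1.0, p))
  expect_error(kir_params(v_c = 0), "v_c")
})

test_that("an undriven MSN rests quietly below threshold", {
  n <- round(1500 / 0.025)
  res <- simulate_msn(msn_params(), rep(0, n), dt = 0.025)
  expect_equal(res$spike_count, 0)
  expect_lt(res$mean_v, -60)
  expect_equal(nrow(res$trace) > 10, TRUE)
})

test_that("MSN excitability is monotone in cortical drive", {
  n <- round(1500 / 0.025)
  rates <- vapply(c(0.04, 0.08, 0.15, 0.3), function(d) {
    simulate_msn(msn_params(), rep(d, n), dt = 0.025, seed = 5)$rate_hz
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
  # a closed gate silences the drive entirely
  gated <- simulate_msn(msn_params(), rep(0.3, n),
                        gating_drive = rep(0, n), dt = 0.025, seed = 5)
  expect_equal(gated$spike_count, 0)
})

test_that("class-specific neuromodulation shifts MSN output as coupled", {
  n <- round(1500 / 0.025)
  drive <- rep(0.12, n)
  base <- simulate_msn(msn_params("SP_D1"), drive, dt = 0.025, seed = 2)
  d1 <- simulate_msn(msn_params("SP_D1"), drive,
                     m = modulation_state(D1 = 0.4), dt = 0.025, seed = 2)
  # D1 strengthens Kir2: the down-state is stabilised, firing not higher
  expect_lte(d1$spike_count, base$spike_count)
  # D2 activation in Enk cells reduces presynaptic glutamate
  base2 <- simulate_msn(msn_params("Enk_D2"), drive, dt = 0.025, seed = 2)
  d2 <- simulate_msn(msn_params("Enk_D2"), drive,
                     m = modulation_state(D2 = 0.5), dt = 0.025, seed = 2)
  expect_lte(d2$spike_count, base2$spike_count)
  # D1 has no coupling in Enk_D2 cells
  d1_on_enk <- simulate_msn(msn_params("Enk_D2"), drive,
                            m = modulation_state(D1 = 0.4), dt = 0.025,
                            seed = 2)
  expect_equal(d1_on_enk$spike_count, base2$spike_count)
})

test_that("the striatal population readout is a weighted linear mean", {
  mk <- function(x) list(excitability = x)
  cells <- list(mk(0), mk(0), mk(0))
  expect_equal(striatal_population_readout(cells,
                                           c("SP_D1", "Enk_D2", "dual")),
               0)
  expect_equal(striatal_population_readout(list(mk(7)), "SP_D1"), 7)
  r1 <- striatal_population_readout(list(mk(2), mk(4), mk(6)),
                                    c("SP_D1", "SP_D1", "Enk_D2"))
  r2 <- striatal_population_readout(list(mk(4), mk(8), mk(12)),
                                    c("SP_D1", "SP_D1", "Enk_D2"))
  expect_equal(r2, 2 * r1)
  # non-equal class weights
  r3 <- striatal_population_readout(list(mk(2), mk(6)),
                                    c("SP_D1", "Enk_D2"),
                                    weights = c(SP_D1 = 3, Enk_D2 = 1))
  expect_equal(r3, (3 * 2 + 1 * 6) / 4)
  expect_error(striatal_population_readout(list(), character(0)),
               "empty")
})

test_that("dopamine release follows the serotonergic linear map", {
  expect_equal(dopamine_release_scale(modulation_state()), 1)
  expect_equal(dopamine_release_scale(modulation_state(`5HT2C` = -0.2)),
               1.10)
  # combined modulation composes additively
  m <- modulation_state(`5HT2C` = -0.2, `5HT3` = -0.3)
  expect_equal(dopamine_release_scale(m), 1 + 0.5 * 0.2 - 0.5 * 0.3)
  expect_error(modulation_state(D1 = -1), "-1")
})
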