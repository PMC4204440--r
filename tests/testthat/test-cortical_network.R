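short_cfg <- function(seed, ...) {
  network_config(duration = 1500, stim_onset = 800, seed = seed, ...)
}

test_that("pathology scales the lesioned conductances exactly", {
  cfg <- network_config()
  # all-zero pathology is the identity
  id <- apply_pathology(cfg, pathology_config(0, 0, 0, 0))
  expect_equal(unclass(id), unclass(cfg))
  p <- pathology_config(nmda_reduction = 0.2, gaba_reduction = 0.1,
                        da_deficit = 0.5, noise_increase = 0.25)
  out <- apply_pathology(cfg, p)
  expect_equal(out$g_nmda_ee, cfg$g_nmda_ee * 0.8)
  expect_equal(out$g_nmda_ei, cfg$g_nmda_ei * 0.8)
  expect_equal(out$g_gaba_ie, cfg$g_gaba_ie * 0.9)
  expect_equal(out$noise_amp, cfg$noise_amp * 1.25)
  d1 <- cfg$receptor_couplings$receptor == "D1"
  expect_equal(out$receptor_couplings$gain[d1],
               cfg$receptor_couplings$gain[d1] * 0.5)
  # successive applications compose multiplicatively
  twice <- apply_pathology(out, p)
  expect_equal(twice$g_nmda_ee, cfg$g_nmda_ee * 0.8^2)
  expect_equal(twice$noise_amp, cfg$noise_amp * 1.25^2)
  expect_error(pathology_config(nmda_reduction = 1), "reductions")
  expect_error(pathology_config(noise_increase = -0.1), "noise")
})

test_that("receptor effects scale their coupled channels", {
  cfg <- network_config()
  same <- apply_receptor_effects(cfg, c(D1 = 0, M1 = 0))
  expect_equal(unclass(same), unclass(cfg))
  # D1 relative activation +0.1 through gain -0.5 on the slow K+
  out <- apply_receptor_effects(cfg, c(D1 = 0.1))
  expect_equal(out$g_ks_exc, cfg$g_ks_exc * 0.95)
  expect_equal(out$g_hva_exc, cfg$g_hva_exc * 1.05)
  # two receptors converging on one channel stack multiplicatively
  tab <- data.frame(receptor = c("D1", "M1"),
                    target = c("g_ks_exc", "g_ks_exc"),
                    gain = c(-0.5, 0.2))
  out2 <- apply_receptor_effects(cfg, c(D1 = 0.1, M1 = 0.5), tab)
  expect_equal(out2$g_ks_exc, cfg$g_ks_exc * 0.95 * 1.1)
  err <- tryCatch(apply_receptor_effects(cfg, c(H3 = 0.1)),
                  error = conditionMessage)
  expect_match(err, "unknown receptor")
  expect_match(err, "D1")  # the error lists the known receptors
})

test_that("simulations are reproducible seed for seed", {
  a <- simulate_network(short_cfg(42))
  b <- simulate_network(short_cfg(42))
  expect_identical(a$spikes, b$spikes)
  c <- simulate_network(short_cfg(43))
  expect_false(identical(a$spikes, c$spikes))
})

test_that("a disconnected, noiseless network stays at tonic baseline", {
  cfg <- short_cfg(1, g_ampa_ee = 0, g_ampa_ei = 0, g_nmda_ee = 0,
                   g_nmda_ei = 0, g_gaba_ie = 0, g_gaba_ii = 0,
                   noise_rate = 0, stim_amplitude = 0,
                   distractor_rate = 0)
  out <- simulate_network(cfg)
  expect_equal(nrow(out$spikes), 0)
  expect_equal(unique(out$u_e$value), 1)
  expect_equal(unique(out$u_i$value), 1)
})

test_that("population activities are normalised to a unit baseline", {
  out <- simulate_network(short_cfg(7), path = pathology_config())
  pre_e <- out$u_e$value[out$u_e$time > 500 & out$u_e$time < 800]
  pre_i <- out$u_i$value[out$u_i$time > 500 & out$u_i$time < 800]
  expect_equal(mean(pre_e), 1, tolerance = 0.01)
  expect_equal(mean(pre_i), 1, tolerance = 0.01)
})

test_that("raising interneuron NMDA drive never favours pyramidal firing", {
  diffs <- vapply(1:20, function(s) {
    cfg <- short_cfg(s)
    base <- simulate_network(cfg)$rate_exc
    up <- cfg
    up$g_nmda_ei <- cfg$g_nmda_ei * 1.3
    up <- glyqsp:::validate_network_config(up)
    simulate_network(up)$rate_exc - base
  }, numeric(1))
  bt <- binom.test(sum(diffs < 0), sum(diffs != 0),
                   alternative = "greater")
  expect_lt(bt$p.value, 0.05)
})

test_that("raising recurrent e-e NMDA does not lower pyramidal firing", {
  diffs <- vapply(1:10, function(s) {
    cfg <- short_cfg(s)
    base <- simulate_network(cfg)$rate_exc
    up <- cfg
    up$g_nmda_ee <- cfg$g_nmda_ee * 1.2
    up <- glyqsp:::validate_network_config(up)
    simulate_network(up)$rate_exc - base
  }, numeric(1))
  expect_gte(mean(diffs), 0)
  expect_gte(sum(diffs >= 0), 8)
})

test_that("glycine scaling routes through the synapse-class potentiation", {
  pd <- pd_beneficial()
  cfg <- short_cfg(3)
  at_star <- simulate_network(cfg, gly = 1.1, pd = pd)
  # identical to manually pre-scaling the NMDA conductances
  manual <- cfg
  manual$g_nmda_ee <- cfg$g_nmda_ee * effective_conductance(1.1, "ee", pd)
  manual$g_nmda_ei <- cfg$g_nmda_ei * effective_conductance(1.1, "ei", pd)
  manual <- glyqsp:::validate_network_config(manual)
  expect_identical(at_star$spikes, simulate_network(manual)$spikes)
  expect_error(simulate_network(cfg, gly = 1.1), "pd")
})

test_that("spike trains persist as delimited text", {
  out <- simulate_network(short_cfg(9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spikes(out, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(out$spikes))
  expect_equal(back$time_ms, out$spikes$time_ms)
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(dt = 0.2), "dt")
  expect_error(network_config(duration = 1000, stim_onset = 2000),
               "duration")
  expect_error(network_config(p_ee = 1.5), "probabilities")
})
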