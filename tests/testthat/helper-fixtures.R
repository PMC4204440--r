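# shared pharmacodynamic fixtures
pd_reference <- function() {
  synapse_class_pd(ee = hill_params(0.35, 1.84),
                   ei = hill_params(0.25, 1.1))
}

pd_beneficial <- function() {
  synapse_class_pd(ee = hill_params(0.35, 2), ei = hill_params(0.2, 1))
}

pd_flat <- function() {
  synapse_class_pd(ee = hill_params(0.3, 1.5), ei = hill_params(0.3, 1.5))
}

# independent brute-force oracle for the e-i/e-e ratio minimum: direct
# Hill arithmetic on a dense log grid, no package search code involved
oracle_ratio_min <- function(ee_ec50, ee_slope, ei_ec50, ei_slope,
                             window = c(0.01, 100), n = 1e5) {
  g <- exp(seq(log(window[1]), log(window[2]), length.out = n))
  act <- function(x, ec50, s) x^s / (x^s + ec50^s)
  r <- act(g, ei_ec50, ei_slope) / act(g, ee_ec50, ee_slope)
  i <- which.min(r)
  list(gly = g[i], ratio = r[i], interior = i > 1 && i < n,
       step = g[2] / g[1])
}
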