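test_that("equilibrium glycine follows the cotransporter free energy", {
  # zero driving force: extracellular equals intracellular glycine
  flat <- ion_conditions(na_in = 140, na_out = 140, cl_in = 120,
                         cl_out = 120, gly_in = 2, vm = 0)
  expect_equal(equilibrium_glycine_out(flat), 2 * 1000)
  # independent hand computation: set the summed electrochemical free
  # energy of one 2Na+/Cl-/Gly cycle to zero and solve
  c1 <- ion_conditions(na_in = 15, cl_in = 12, gly_in = 2, vm = -40)
  want <- 2 * (15 / 140)^2 * (12 / 120) *
    exp(96485.33212 * -0.040 / (8.31446262 * 310)) * 1000
  expect_equal(equilibrium_glycine_out(c1), want)
  expect_equal(equilibrium_glycine_out(c1), 0.51, tolerance = 1e-2)
})

test_that("equilibrium glycine is monotone in every driving variable", {
  set.seed(21)
  for (k in 1:30) {
    base <- list(na_in = runif(1, 5, 30), na_out = runif(1, 100, 160),
                 cl_in = runif(1, 3, 20), cl_out = runif(1, 80, 160),
                 gly_in = runif(1, 0.2, 5), vm = runif(1, -90, -20))
    g0 <- equilibrium_glycine_out(do.call(ion_conditions, base))
    bump <- function(field, f) {
      b <- base
      b[[field]] <- b[[field]] * f
      equilibrium_glycine_out(do.call(ion_conditions, b))
    }
    expect_gt(bump("na_in", 1.1), g0)
    expect_gt(bump("cl_in", 1.1), g0)
    expect_gt(bump("gly_in", 1.1), g0)
    expect_lt(bump("na_out", 1.1), g0)
    expect_lt(bump("cl_out", 1.1), g0)
    # less negative potential (inward +1 charge) raises the ceiling
    b <- base; b$vm <- b$vm + 10
    expect_gt(equilibrium_glycine_out(do.call(ion_conditions, b)), g0)
    # doubling intracellular glycine doubles the ceiling exactly
    expect_equal(bump("gly_in", 2), 2 * g0)
  }
})

test_that("the physiological box maximum matches a grid search", {
  mx <- max_equilibrium_over_ranges()
  grid <- expand.grid(na_in = seq(10, 20, length.out = 6),
                      cl_in = seq(6, 12, length.out = 6),
                      gly_in = seq(0.5, 5, length.out = 6),
                      vm = seq(-75, -40, length.out = 6))
  vals <- apply(grid, 1, function(r) {
    equilibrium_glycine_out(ion_conditions(
      na_in = r["na_in"], cl_in = r["cl_in"], gly_in = r["gly_in"],
      vm = r["vm"]))
  })
  expect_equal(mx$gly_out_uM, max(vals))
  top <- grid[which.max(vals), ]
  expect_equal(unname(unlist(top)), c(20, 12, 5, -40))
  expect_equal(mx$corner$na_in, 20)
  # degenerate ranges reduce to a single evaluation
  pt <- max_equilibrium_over_ranges(na_in = c(15, 15), cl_in = c(12, 12),
                                    gly_in = c(2, 2), vm = c(-40, -40))
  expect_equal(pt$gly_out_uM, equilibrium_glycine_out(
    ion_conditions(na_in = 15, cl_in = 12, gly_in = 2, vm = -40)))
  expect_error(max_equilibrium_over_ranges(na_in = c(20, 10)), "range")
})

test_that("Michaelis-Menten uptake behaves at its landmarks", {
  k <- transporter_kinetics(km = 15, turnover = 10, density = 1)
  expect_equal(mm_uptake_rate(15, k), 5)
  expect_equal(mm_uptake_rate(0, k), 0)
  expect_equal(mm_uptake_rate(5, k), 10 * 5 / 20)
  expect_error(mm_uptake_rate(-1, k), "gly_out")
  expect_error(transporter_kinetics(km = -1), "km")
})

test_that("invalid ionic conditions are rejected", {
  expect_error(ion_conditions(na_in = -5, cl_in = 12, gly_in = 2,
                              vm = -40), "concentrations")
  expect_error(ion_conditions(na_in = 15, cl_in = 12, gly_in = 2,
                              vm = -40, temperature = 350), "temperature")
})

test_that("transporter sweeps evaluate and persist scenario tables", {
  sc <- data.frame(na_in = c(10, 20), cl_in = c(6, 12),
                   gly_in = c(0.5, 5), vm = c(-75, -40))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- transporter_sweep(sc, path)
  expect_equal(out$gly_out_uM[2], max_equilibrium_over_ranges()$gly_out_uM)
  back <- read.delim(path)
  expect_equal(back$gly_out_uM, out$gly_out_uM)
})
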