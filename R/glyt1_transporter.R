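#' Ionic conditions constraining the GlyT1 cotransporter
#'
#' GlyT1 moves 2 Na+, 1 Cl- and one glycine inward per cycle (net +1
#' charge), so the extracellular glycine it can sustain at equilibrium
#' is fixed by the transmembrane Na+ and Cl- gradients, the
#' intracellular glycine pool and the membrane potential. The
#' transporter is predominantly astrocytic; the default potential
#' window used elsewhere reflects astrocyte resting values.
#'
#' @param na_in,na_out Intra/extracellular Na+ (mM), > 0.
#' @param cl_in,cl_out Intra/extracellular Cl- (mM), > 0.
#' @param gly_in Intracellular glycine (mM), > 0.
#' @param vm Membrane potential, inside minus outside (mV).
#' @param temperature Absolute temperature (K), in `[273, 320]`.
#' @return An object of class `ion_conditions`.
#' @examples
#' ion_conditions(na_in = 15, cl_in = 12, gly_in = 2, vm = -40)
#' @export
ion_conditions <- function(na_in, na_out = 140, cl_in, cl_out = 120,
                           gly_in, vm, temperature = 310) {
  vals <- c(na_in = na_in, na_out = na_out, cl_in = cl_in,
            cl_out = cl_out, gly_in = gly_in)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all concentrations must be finite and > 0")
  }
  if (!is.finite(vm)) stop("'vm' must be finite")
  if (temperature < 273 || temperature > 320) {
    stop("'temperature' must be in [273, 320] K")
  }
  structure(list(na_in = na_in, na_out = na_out, cl_in = cl_in,
                 cl_out = cl_out, gly_in = gly_in, vm = vm,
                 temperature = temperature),
            class = "ion_conditions")
}

# Faraday and gas constants (SI); RT/F is computed, never hard-coded.
.FARADAY <- 96485.33212
.GAS_R <- 8.31446262

#' Equilibrium extracellular glycine set by GlyT1 thermodynamics
#'
#' Sets the summed electrochemical free energy of one 2Na+/Cl-/glycine
#' cycle to zero and solves for extracellular glycine:
#' \deqn{Gly_{out} = Gly_{in}\,(Na_{in}/Na_{out})^2\,(Cl_{in}/Cl_{out})
#'   \, e^{F V_m / (R T)}}
#' with a net inward charge of +1 per cycle. More negative membrane
#' potential, lower intracellular Na+/Cl-/glycine, or higher
#' extracellular Na+/Cl- all lower the sustainable extracellular
#' glycine.
#'
#' @param c An [ion_conditions] object.
#' @return Equilibrium extracellular glycine in uM.
#' @examples
#' equilibrium_glycine_out(ion_conditions(na_in = 15, cl_in = 12,
#'                                        gly_in = 2, vm = -40))
#' @export
equilibrium_glycine_out <- function(c) {
  stopifnot(inherits(c, "ion_conditions"))
  vm_volts <- c$vm / 1000
  factor <- (c$na_in / c$na_out)^2 * (c$cl_in / c$cl_out) *
    exp(.FARADAY * vm_volts / (.GAS_R * c$temperature))
  c$gly_in * factor * 1000  # mM -> uM
}

#' Maximum equilibrium glycine over physiological ranges
#'
#' Every factor of the equilibrium relation is monotone, so the maximum
#' over a box of conditions is attained at the corner with the largest
#' intracellular Na+, Cl- and glycine and the least negative membrane
#' potential. Evaluates that corner analytically and reports it.
#'
#' Note: reported intracellular Cl- values for astrocytes differ
#' between sources (6 vs 12 mM); the default range spans both rather
#' than silently picking one. The astrocyte potential window unions the
#' reported -75 mV resting value and the -50 to -70 mV steady-state
#' range.
#'
#' @param na_in,cl_in,vm Length-2 ranges (mM, mM, mV).
#' @param gly_in Length-2 range of intracellular glycine (mM).
#' @param na_out,cl_out,temperature Fixed extracellular conditions.
#' @return A list with `gly_out_uM` (the maximum) and `corner` (the
#'   maximising [ion_conditions]).
#' @examples
#' max_equilibrium_over_ranges()$gly_out_uM  # stays below 10 uM
#' @export
max_equilibrium_over_ranges <- function(na_in = c(10, 20),
                                        cl_in = c(6, 12),
                                        gly_in = c(0.5, 5),
                                        vm = c(-75, -40),
                                        na_out = 140, cl_out = 120,
                                        temperature = 310) {
  chk <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop("'", nm, "' must be an ordered length-2 range")
    }
  }
  chk(na_in, "na_in"); chk(cl_in, "cl_in")
  chk(gly_in, "gly_in"); chk(vm, "vm")
  corner <- ion_conditions(na_in = na_in[2], na_out = na_out,
                           cl_in = cl_in[2], cl_out = cl_out,
                           gly_in = gly_in[2], vm = vm[2],
                           temperature = temperature)
  list(gly_out_uM = equilibrium_glycine_out(corner), corner = corner)
}

#' GlyT1 kinetic parameters
#'
#' @param km Michaelis constant for extracellular glycine (uM), > 0;
#'   reported values fall in 10-20 uM.
#' @param turnover Transport cycles per second per transporter, > 0;
#'   GlyT1 is slow, about 10/s.
#' @param density Relative transporter density (dimensionless).
#' @return An object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(km = 15, turnover = 10, density = 1) {
  if (km <= 0) stop("'km' must be > 0")
  if (turnover <= 0) stop("'turnover' must be > 0")
  if (density < 0) stop("'density' must be >= 0")
  structure(list(km = km, turnover = turnover, density = density),
            class = "transporter_kinetics")
}

#' Michaelis-Menten glycine uptake rate
#'
#' `density * turnover * gly_out / (gly_out + km)`, in relative
#' units per second.
#'
#' @param gly_out Extracellular glycine (uM), >= 0. Vectorised.
#' @param k A [transporter_kinetics] object.
#' @return Uptake rate, same length as `gly_out`.
#' @export
mm_uptake_rate <- function(gly_out, k = transporter_kinetics()) {
  stopifnot(inherits(k, "transporter_kinetics"))
  if (any(gly_out < 0)) stop("'gly_out' must be >= 0")
  k$density * k$turnover * gly_out / (gly_out + k$km)
}

#' Sweep equilibrium glycine over ion-condition scenarios
#'
#' Evaluates [equilibrium_glycine_out] for every row of a scenario
#' table and optionally writes the result as tab-delimited text.
#'
#' @param scenarios Data frame with columns matching the arguments of
#'   [ion_conditions] (missing columns take the defaults).
#' @param path Optional output path.
#' @return The scenario table with an added `gly_out_uM` column.
#' @export
transporter_sweep <- function(scenarios, path = NULL) {
  defaults <- list(na_out = 140, cl_out = 120, temperature = 310)
  res <- vapply(seq_len(nrow(scenarios)), function(i) {
    row <- as.list(scenarios[i, , drop = FALSE])
    args <- utils::modifyList(defaults, row)
    equilibrium_glycine_out(do.call(ion_conditions, args))
  }, numeric(1))
  out <- cbind(scenarios, gly_out_uM = res)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out
}
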